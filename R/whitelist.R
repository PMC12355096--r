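# CHIP whitelist: which (gene, protein-change) candidates are considered
# CHIP at all, which are exempt from the germline binomial test, and which
# are named sequencing/germline artifacts.

#' Load a CHIP whitelist
#'
#' Reads a tab-separated whitelist with columns `kind`, `gene`, `hgvs_p`,
#' `consequence`, `artifact_mode`. Four record kinds are understood:
#' \describe{
#'   \item{site}{an exact (gene, protein change) entry;}
#'   \item{rule}{a gene-level rule matching consequence classes
#'     (e.g. any frameshift/nonsense/splice variant in ASXL1);}
#'   \item{exemption}{a site entry additionally exempt from the
#'     binomial VAF-0.5 somatic-consistency test;}
#'   \item{artifact}{a named artifact to remove, either `always` or only
#'     at `low_vaf` (VAF < 0.1).}
#' }
#' The packaged default list is a documented stand-in: published CHIP
#' pipelines defer their exact prespecified lists to prior work, so the
#' file shipped under `inst/extdata` holds representative hotspot entries
#' and loss-of-function rules, and is meant to be replaced or extended by
#' the user.
#'
#' @param path Path to a whitelist TSV. Defaults to the packaged list.
#' @return An object of class `chip_whitelist`: a list with data frames
#'   `sites`, `rules`, `exemptions`, `artifacts`.
#' @export
load_whitelist <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "chip_whitelist.tsv", package = "chcv",
                        mustWork = TRUE)
  }
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  assert_columns(raw, c("kind", "gene", "hgvs_p", "consequence"), "whitelist")
  bad <- setdiff(unique(raw$gene), chip_panel_genes())
  if (length(bad)) {
    stop("whitelist contains genes outside the 11-gene CHIP panel: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sites <- raw[raw$kind %in% c("site", "exemption"),
               c("gene", "hgvs_p", "consequence")]
  rules <- raw[raw$kind == "rule", c("gene", "consequence")]
  exemptions <- raw[raw$kind == "exemption", c("gene", "hgvs_p")]
  artifacts <- raw[raw$kind == "artifact", c("gene", "hgvs_p", "artifact_mode")]
  if (nrow(artifacts) && nrow(exemptions)) {
    clash <- merge(artifacts, exemptions, by = c("gene", "hgvs_p"))
    if (nrow(clash)) {
      stop("whitelist artifacts overlap binomial-test exemptions",
           call. = FALSE)
    }
  }
  structure(
    list(sites = sites, rules = rules, exemptions = exemptions,
         artifacts = artifacts, path = path),
    class = "chip_whitelist"
  )
}

#' @export
print.chip_whitelist <- function(x, ...) {
  cat("CHIP whitelist:", nrow(x$sites), "site entries,",
      nrow(x$rules), "gene rules,", nrow(x$exemptions), "binomial exemptions,",
      nrow(x$artifacts), "named artifacts\n")
  invisible(x)
}

#' Match candidate variants against the whitelist
#'
#' A variant matches if its (gene, protein change) is a site entry, or if
#' its gene has a rule covering the variant's consequence class. Genes
#' outside the 11-gene panel are an error: upstream restriction to the
#' panel is part of the calling contract.
#'
#' @param gene Character vector of gene symbols.
#' @param hgvs_p Character vector of protein changes (e.g. `"p.R882H"`).
#' @param consequence Character vector in
#'   `c("missense","frameshift","nonsense","splice","other")`.
#' @param wl A `chip_whitelist`.
#' @return Logical vector, `TRUE` where the variant is whitelisted.
#' @export
match_whitelist <- function(gene, hgvs_p, consequence, wl) {
  stopifnot(inherits(wl, "chip_whitelist"))
  n <- length(gene)
  stopifnot(length(hgvs_p) == n, length(consequence) == n)
  out_panel <- !gene %in% chip_panel_genes()
  if (any(out_panel)) {
    stop("gene(s) outside the 11-gene CHIP panel: ",
         paste(unique(gene[out_panel]), collapse = ", "), call. = FALSE)
  }
  site_key <- paste(wl$sites$gene, wl$sites$hgvs_p)
  hit_site <- paste(gene, hgvs_p) %in% site_key
  hit_rule <- rep(FALSE, n)
  for (i in seq_len(nrow(wl$rules))) {
    cls <- strsplit(wl$rules$consequence[i], ",", fixed = TRUE)[[1]]
    hit_rule <- hit_rule | (gene == wl$rules$gene[i] & consequence %in% cls)
  }
  hit_site | hit_rule
}

is_binomial_exempt <- function(gene, hgvs_p, wl) {
  paste(gene, hgvs_p) %in% paste(wl$exemptions$gene, wl$exemptions$hgvs_p)
}
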