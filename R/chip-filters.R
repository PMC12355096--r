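# Per-variant filters of the CHIP post-calling cascade. Each filter is a
# pure function of the variant record (plus whitelist where relevant), so
# verdicts commute and an audit trail can list every failed rule, not just
# the first. All take the variant-evidence data frame and return a verdict
# data frame aligned row-for-row.

#' Validate a variant-evidence table
#'
#' Checks the invariants of read-level evidence for candidate somatic
#' variants: `0 <= ad <= dp`, `vaf == ad / dp`, `f1r2 + f2r1 <= ad`,
#' genes restricted to the 11-gene panel, no duplicated
#' (participant, variant) records, and a reference-context window of odd
#' length covering at least +/- 5 bases around the variant position.
#'
#' @param evidence Data frame with columns `participant_id`, `gene`,
#'   `hgvs_p`, `chrom`, `pos`, `ref`, `alt`, `dp`, `ad`, `f1r2`, `f2r1`,
#'   `vaf`, `context`, `consequence`.
#' @param check_unique Also require unique (participant, variant) records
#'   (the contract of [call_chip()]; per-variant filters accept any rows).
#' @return The validated data frame, invisibly.
#' @export
validate_variant_evidence <- function(evidence, check_unique = FALSE) {
  assert_columns(evidence,
                 c("participant_id", "gene", "hgvs_p", "chrom", "pos",
                   "ref", "alt", "dp", "ad", "f1r2", "f2r1", "vaf",
                   "context", "consequence"),
                 "variant evidence")
  if (nrow(evidence) == 0) return(invisible(evidence))
  with(evidence, {
    if (any(ad < 0 | ad > dp)) stop("ad must satisfy 0 <= ad <= dp", call. = FALSE)
    if (any(abs(vaf - ad / dp) > 1e-9)) stop("vaf must equal ad / dp", call. = FALSE)
    if (any(f1r2 + f2r1 > ad)) stop("f1r2 + f2r1 must not exceed ad", call. = FALSE)
  })
  bad <- !evidence$gene %in% chip_panel_genes()
  if (any(bad)) {
    stop("gene(s) outside the 11-gene CHIP panel: ",
         paste(unique(evidence$gene[bad]), collapse = ", "), call. = FALSE)
  }
  if (check_unique) {
    key <- paste(evidence$participant_id, evidence$chrom, evidence$pos,
                 evidence$ref, evidence$alt)
    if (anyDuplicated(key)) {
      stop("duplicate (participant, variant) records in evidence",
           call. = FALSE)
    }
  }
  nc <- nchar(evidence$context)
  if (any(nc < 11 | nc %% 2 == 0)) {
    stop("context must be an odd-length window of >= 11 bases centred on pos",
         call. = FALSE)
  }
  invisible(evidence)
}

verdict <- function(kept, rule, detail = rep(NA_real_, length(kept))) {
  data.frame(kept = kept,
             failed_rules = ifelse(kept, "", rule),
             detail = detail,
             stringsAsFactors = FALSE)
}

#' Sequencing-depth filter
#'
#' Keeps a variant only with total depth DP >= 20, alt depth AD >= 5, and
#' at least one alt-supporting read pair in each orientation class
#' (F1R2 >= 1 and F2R1 >= 1), guarding against strand-specific artifacts.
#'
#' @param evidence Variant-evidence data frame (see
#'   [validate_variant_evidence()]).
#' @return Verdict data frame with columns `kept`, `failed_rules`.
#' @export
depth_filter <- function(evidence) {
  validate_variant_evidence(evidence)
  fails <- cbind(depth_dp = evidence$dp < 20,
                 depth_ad = evidence$ad < 5,
                 depth_f1r2 = evidence$f1r2 < 1,
                 depth_f2r1 = evidence$f2r1 < 1)
  kept <- rowSums(fails) == 0
  rule <- apply(fails, 1, function(f) paste(colnames(fails)[f], collapse = ";"))
  verdict(kept, rule)
}

# Does the centre base of `context` sit inside, or immediately adjacent
# to, a run of >= `min_run` identical bases?
in_homopolymer <- function(context, min_run = 5) {
  vapply(context, function(ctx) {
    ch <- strsplit(ctx, "", fixed = TRUE)[[1]]
    centre <- (length(ch) + 1L) / 2L
    r <- rle(ch)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    long <- which(r$lengths >= min_run)
    any(starts[long] - 1L <= centre & centre <= ends[long] + 1L)
  }, logical(1), USE.NAMES = FALSE)
}

#' Homopolymer-run filter
#'
#' Sites inside (or immediately adjacent to) a run of five or more
#' identical reference bases are prone to polymerase-slippage artifacts;
#' such sites are removed unless supported by AD >= 10 and VAF >= 0.08.
#' Sites outside homopolymer runs are untouched by this rule.
#'
#' @inheritParams depth_filter
#' @return Verdict data frame.
#' @export
homopolymer_filter <- function(evidence) {
  validate_variant_evidence(evidence)
  in_run <- in_homopolymer(evidence$context)
  kept <- !in_run | (evidence$ad >= 10 & evidence$vaf >= 0.08)
  verdict(kept, "homopolymer")
}

#' Named-artifact filter
#'
#' Removes recurrent artifact calls known from blood-sequencing CHIP
#' pipelines: TP53 p.P72R (a common germline polymorphism) and ASXL1
#' p.P815L unconditionally, and the ASXL1 p.G646Wfs*12 hotspot only when
#' VAF < 0.1 (small apparent clones at that indel-prone site are
#' artifactual; large clones are genuine CHIP). `scope = "all"` instead
#' applies the VAF < 0.1 condition to all three named variants.
#'
#' @inheritParams depth_filter
#' @param wl A `chip_whitelist` carrying the artifact entries.
#' @param scope `"g646fs"` (default: VAF condition on ASXL1 p.G646Wfs*12
#'   only) or `"all"` (VAF condition on every named artifact).
#' @return Verdict data frame.
#' @export
named_artifact_filter <- function(evidence, wl, scope = c("g646fs", "all")) {
  validate_variant_evidence(evidence)
  scope <- match.arg(scope)
  stopifnot(inherits(wl, "chip_whitelist"))
  kept <- rep(TRUE, nrow(evidence))
  key <- paste(evidence$gene, evidence$hgvs_p)
  for (i in seq_len(nrow(wl$artifacts))) {
    hit <- key == paste(wl$artifacts$gene[i], wl$artifacts$hgvs_p[i])
    conditional <- scope == "all" || wl$artifacts$artifact_mode[i] == "low_vaf"
    remove <- if (conditional) hit & evidence$vaf < 0.1 else hit
    kept <- kept & !remove
  }
  verdict(kept, "named_artifact")
}

#' Binomial somatic-consistency test
#'
#' Missense variants in CBL, TET2, DNMT3A and TP53 whose allele fraction
#' is statistically indistinguishable from the germline expectation of
#' 0.5 are removed: an exact two-sided binomial test of `ad` successes in
#' `dp` trials against probability 0.5 is computed, and the variant is
#' removed when p >= 0.01 (i.e. when the evidence cannot rule out a
#' germline call). Three TET2 variants (p.H1904R, p.I1873T, p.T1884A)
#' are exempt, being established CHIP variants that can drift toward
#' high allele fractions. Variants outside the four genes, non-missense
#' variants and exempt variants pass through unchanged with `detail = NA`.
#'
#' @inheritParams depth_filter
#' @param wl A `chip_whitelist` carrying the exemption set.
#' @return Verdict data frame; `detail` holds the binomial p-value where
#'   the test applied.
#' @export
binomial_somatic_test <- function(evidence, wl) {
  validate_variant_evidence(evidence)
  stopifnot(inherits(wl, "chip_whitelist"))
  if (nrow(evidence) && any(evidence$dp == 0)) {
    stop("dp = 0: cannot test somatic consistency", call. = FALSE)
  }
  applies <- evidence$consequence == "missense" &
    evidence$gene %in% c("CBL", "TET2", "DNMT3A", "TP53") &
    !is_binomial_exempt(evidence$gene, evidence$hgvs_p, wl)
  p <- rep(NA_real_, nrow(evidence))
  idx <- which(applies)
  if (length(idx)) {
    # p depends only on (ad, dp); compute once per distinct pair
    pair <- paste(evidence$ad[idx], evidence$dp[idx])
    up <- !duplicated(pair)
    pv <- vapply(idx[up], function(i) {
      stats::binom.test(evidence$ad[i], evidence$dp[i], p = 0.5)$p.value
    }, numeric(1))
    p[idx] <- pv[match(pair, pair[up])]
  }
  kept <- !applies | (p < 0.01)
  kept[is.na(kept)] <- TRUE
  verdict(kept, "binomial_germline", detail = p)
}

#' Cohort-level recurrence filter
#'
#' A variant surviving the per-variant filters in more than 20
#' participants is suspect unless it carries a signature of age-related
#' positive selection: carrier status is regressed (logistic, one
#' covariate at a time) on baseline age and on TERT rs7705526 dosage, and
#' the variant is retained only if the association p-value is <= 0.1.
#' `combine = "either"` (default) requires either test to pass;
#' `"both"` requires both. Variants in at most 20 participants are kept
#' without testing. On non-convergence or separation, a Fisher exact test
#' on the dichotomised covariate (age above cohort median; any TERT risk
#' allele) is used instead and flagged in `details`.
#'
#' @param variant_key Character vector (one per kept variant record)
#'   identifying the variant, e.g. `"chr2:25234373:C:T"`.
#' @param participant_id Character vector parallel to `variant_key`.
#' @param phenotypes Data frame with `participant_id`, `age_baseline`,
#'   `tert_dosage` for the whole cohort (carriers and non-carriers).
#' @param combine `"either"` or `"both"`.
#' @param max_carriers Carrier count above which the test applies
#'   (default 20).
#' @param alpha Association p-value threshold (default 0.1).
#' @return Data frame with one row per distinct variant: `variant_key`,
#'   `n_carriers`, `tested`, `p_age`, `p_tert`, `fallback`, `kept`.
#' @export
recurrence_filter <- function(variant_key, participant_id, phenotypes,
                              combine = c("either", "both"),
                              max_carriers = 20, alpha = 0.1) {
  combine <- match.arg(combine)
  assert_columns(phenotypes, c("participant_id", "age_baseline", "tert_dosage"),
                 "phenotypes")
  keys <- sort(unique(variant_key))
  nk <- length(keys)
  out <- data.frame(variant_key = keys,
                    n_carriers = rep(NA_integer_, nk),
                    tested = rep(FALSE, nk),
                    p_age = rep(NA_real_, nk), p_tert = rep(NA_real_, nk),
                    fallback = rep(FALSE, nk), kept = rep(TRUE, nk),
                    stringsAsFactors = FALSE)
  age_hi <- phenotypes$age_baseline > stats::median(phenotypes$age_baseline)
  for (j in seq_along(keys)) {
    carriers <- unique(participant_id[variant_key == keys[j]])
    out$n_carriers[j] <- length(carriers)
    if (length(carriers) <= max_carriers) next
    out$tested[j] <- TRUE
    y <- as.integer(phenotypes$participant_id %in% carriers)
    pvals <- vapply(list(phenotypes$age_baseline, phenotypes$tert_dosage),
                    function(x) assoc_p(y, x), numeric(1))
    if (anyNA(pvals)) {
      out$fallback[j] <- TRUE
      pvals <- c(stats::fisher.test(table(y, age_hi))$p.value,
                 stats::fisher.test(table(y, phenotypes$tert_dosage > 0))$p.value)
    }
    out$p_age[j] <- pvals[1]
    out$p_tert[j] <- pvals[2]
    out$kept[j] <- if (combine == "either") min(pvals) <= alpha
                   else max(pvals) <= alpha
  }
  out
}

# Wald p for the slope of a univariable logistic regression; NA signals
# separation or non-convergence (caller falls back to Fisher).
assoc_p <- function(y, x) {
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  co <- summary(fit)$coefficients
  if (!fit$converged || nrow(co) < 2 || abs(co[2, 1]) > 15) return(NA_real_)
  co[2, 4]
}
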