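# The full CHIP post-calling cascade: whitelist match -> depth ->
# homopolymer -> named artifacts -> binomial somatic test -> cohort
# recurrence, then per-participant aggregation.

#' Call CHIP status from candidate variant evidence
#'
#' Applies the post-calling filter cascade to candidate somatic variants
#' in the 11-gene CHIP panel and aggregates the surviving calls into a
#' per-participant CHIP status. The per-variant rules (depth,
#' homopolymer, named artifact, binomial somatic-consistency) each depend
#' only on the variant record, so every rule is evaluated for every
#' whitelisted variant and the audit table lists all failed rules. The
#' cohort-level recurrence rule then tests variants carried by more than
#' 20 participants for association with age and TERT rs7705526.
#'
#' @param evidence Variant-evidence data frame
#'   (see [validate_variant_evidence()]).
#' @param wl A `chip_whitelist` (default: packaged list).
#' @param phenotypes Data frame with `participant_id`, `age_baseline`,
#'   `tert_dosage` for every cohort participant; participants with no
#'   candidate variants must be present to receive a non-carrier status.
#' @param artifact_scope Passed to [named_artifact_filter()].
#' @param recurrence_combine Passed to [recurrence_filter()].
#' @param expanded_vaf VAF threshold for the expanded-clone flag
#'   (default 0.10).
#' @return A list of class `chip_call_set`:
#' \describe{
#'   \item{status}{one row per phenotype participant: `participant_id`,
#'     `carrier`, `n_mutations`, `genes` (comma-joined), `max_vaf`,
#'     `expanded`, `mutation_count_class` (`"0"`,`"1"`,`"2"`,`"3+"`);}
#'   \item{calls}{surviving variant calls;}
#'   \item{audit}{every candidate with its verdicts: `whitelisted`,
#'     per-rule `kept` flags, `binom_p`, `failed_rules`, `kept`.}
#'   \item{recurrence}{per-variant recurrence-test table.}
#' }
#' @export
call_chip <- function(evidence, wl = load_whitelist(), phenotypes,
                      artifact_scope = c("g646fs", "all"),
                      recurrence_combine = c("either", "both"),
                      expanded_vaf = 0.10) {
  artifact_scope <- match.arg(artifact_scope)
  recurrence_combine <- match.arg(recurrence_combine)
  validate_variant_evidence(evidence, check_unique = TRUE)
  assert_columns(phenotypes, "participant_id", "phenotypes")

  n <- nrow(evidence)
  audit <- evidence[, c("participant_id", "gene", "hgvs_p",
                        "chrom", "pos", "ref", "alt", "vaf")]
  if (n) {
    audit$whitelisted <- match_whitelist(evidence$gene, evidence$hgvs_p,
                                         evidence$consequence, wl)
    v_depth <- depth_filter(evidence)
    v_homo <- homopolymer_filter(evidence)
    v_art <- named_artifact_filter(evidence, wl, scope = artifact_scope)
    v_binom <- binomial_somatic_test(evidence, wl)
    audit$binom_p <- v_binom$detail
    fails <- cbind(
      ifelse(audit$whitelisted, "", "whitelist"),
      v_depth$failed_rules, v_homo$failed_rules,
      v_art$failed_rules, v_binom$failed_rules
    )
    audit$failed_rules <- apply(fails, 1, function(f)
      paste(f[nzchar(f)], collapse = ";"))
    pre_kept <- audit$whitelisted & v_depth$kept & v_homo$kept &
      v_art$kept & v_binom$kept

    key <- paste(evidence$chrom, evidence$pos, evidence$ref, evidence$alt,
                 sep = ":")
    rec <- recurrence_filter(key[pre_kept], evidence$participant_id[pre_kept],
                             phenotypes, combine = recurrence_combine)
    rec_fail <- pre_kept & !key %in% rec$variant_key[rec$kept]
    audit$failed_rules <- ifelse(
      rec_fail,
      paste0(audit$failed_rules,
             ifelse(nzchar(audit$failed_rules), ";", ""), "recurrence"),
      audit$failed_rules)
    audit$kept <- pre_kept & !rec_fail
  } else {
    audit$whitelisted <- logical(0)
    audit$binom_p <- numeric(0)
    audit$failed_rules <- character(0)
    audit$kept <- logical(0)
    rec <- data.frame(variant_key = character(0), n_carriers = integer(0),
                      tested = logical(0), p_age = numeric(0),
                      p_tert = numeric(0), fallback = logical(0),
                      kept = logical(0), stringsAsFactors = FALSE)
  }

  calls <- evidence[audit$kept, , drop = FALSE]
  status <- aggregate_chip_status(calls, phenotypes$participant_id,
                                  expanded_vaf)
  structure(list(status = status, calls = calls, audit = audit,
                 recurrence = rec),
            class = "chip_call_set")
}

aggregate_chip_status <- function(calls, participant_ids, expanded_vaf = 0.10) {
  ids <- as.character(participant_ids)
  status <- data.frame(participant_id = ids,
                       carrier = FALSE, n_mutations = 0L,
                       genes = "", max_vaf = 0,
                       expanded = FALSE,
                       stringsAsFactors = FALSE)
  if (nrow(calls)) {
    sp <- split(calls, calls$participant_id)
    idx <- match(names(sp), status$participant_id)
    if (anyNA(idx)) {
      stop("variant calls for participants absent from phenotypes: ",
           paste(names(sp)[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    status$n_mutations[idx] <- vapply(sp, nrow, integer(1))
    status$genes[idx] <- vapply(sp, function(d)
      paste(sort(unique(d$gene)), collapse = ","), character(1))
    status$max_vaf[idx] <- vapply(sp, function(d) max(d$vaf), numeric(1))
  }
  status$carrier <- status$n_mutations >= 1L
  status$expanded <- status$max_vaf >= expanded_vaf
  status$mutation_count_class <- cut(status$n_mutations, c(-1, 0, 1, 2, Inf),
                                     labels = c("0", "1", "2", "3+"))
  status
}

#' @export
print.chip_call_set <- function(x, ...) {
  cat("CHIP call set:", sum(x$status$carrier), "carriers of",
      nrow(x$calls), "surviving variants among", nrow(x$status),
      "participants;", sum(!x$audit$kept), "candidate records removed\n")
  invisible(x)
}
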