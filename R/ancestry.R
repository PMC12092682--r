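#' Assign a genetic-ancestry superpopulation label from ancestry proportions
#'
#' A participant is assigned the superpopulation whose proportion meets or
#' exceeds `threshold` (inclusive); if no proportion reaches the threshold the
#' participant is labelled `"Admix"`. With the conventional threshold of 0.8
#' at most one component can qualify, since the proportions sum to one.
#'
#' @param proportions Named numeric vector of superpopulation proportions.
#'   Names must be drawn from `AFR`, `EUR`, `EAS`, `SAS`, `AMR`; values must
#'   sum to 1 within `tol`.
#' @param threshold Inclusive assignment threshold, default 0.8.
#' @param tol Tolerance on the unit-sum check, default 1e-6.
#' @return A single character label: one of the five superpopulations or
#'   `"Admix"`.
#' @examples
#' assign_superpopulation(c(EUR = 0.85, AFR = 0.10, SAS = 0.05))
#' assign_superpopulation(c(EUR = 0.5, AFR = 0.3, SAS = 0.2))  # "Admix"
#' @export
assign_superpopulation <- function(proportions, threshold = 0.8, tol = 1e-6) {
  if (is.null(names(proportions)) || any(!nzchar(names(proportions)))) {
    stop("ancestry proportions must be named")
  }
  bad <- setdiff(names(proportions), SUPERPOPULATIONS)
  if (length(bad) > 0) {
    stop("unknown superpopulation label(s): ", paste(bad, collapse = ", "))
  }
  if (any(proportions < -tol) || any(proportions > 1 + tol)) {
    stop("ancestry proportions must lie in [0, 1]")
  }
  if (abs(sum(proportions) - 1) > tol) {
    stop(sprintf("ancestry proportions sum to %.6f, not 1", sum(proportions)))
  }
  hit <- names(proportions)[proportions >= threshold]
  if (length(hit) > 1) {
    # unreachable for threshold > 0.5 with unit sum, but never tie-break silently
    stop("multiple proportions reach the assignment threshold: ",
         paste(hit, collapse = ", "))
  }
  if (length(hit) == 1) hit else "Admix"
}

#' Assign ancestry labels for a whole cohort table
#'
#' Applies [assign_superpopulation()] row-wise to a clinical table carrying
#' per-superpopulation proportion columns.
#'
#' @param tbl Data frame with one column per superpopulation (lower- or
#'   upper-case names among `afr`, `eur`, `eas`, `sas`, `amr`).
#' @param threshold Inclusive assignment threshold, default 0.8.
#' @return Factor of labels with levels `EUR`, `AFR`, `SAS`, `EAS`, `AMR`,
#'   `Admix`, one per row of `tbl`.
#' @export
assign_ancestry <- function(tbl, threshold = 0.8) {
  cols <- intersect(c(SUPERPOPULATIONS, tolower(SUPERPOPULATIONS)), names(tbl))
  if (length(cols) < 2) {
    stop("no superpopulation proportion columns found in table")
  }
  mat <- as.matrix(tbl[, cols, drop = FALSE])
  colnames(mat) <- toupper(cols)
  labels <- vapply(seq_len(nrow(mat)), function(i) {
    assign_superpopulation(mat[i, ], threshold = threshold)
  }, character(1))
  factor(labels, levels = c("EUR", "AFR", "SAS", "EAS", "AMR", "Admix"))
}

#' Default mapping of self-reported ethnicity categories to ancestry labels
#'
#' The mapping used when comparing self-reported ethnicity (SRE) with
#' genetically inferred ancestry; it reflects the broad UK census-style
#' categories and can be replaced wholesale.
#'
#' @return Named character vector, SRE category -> ancestry label.
#' @export
default_sre_mapping <- function() {
  c("White" = "EUR",
    "Black/Black British" = "AFR",
    "Asian/Asian British" = "SAS",
    "Mixed" = "Admix")
}

#' Concordance between self-reported ethnicity and genetic ancestry
#'
#' Maps each self-reported category through `mapping` and counts agreement
#' with the assigned genetic-ancestry labels. Participants with a missing
#' self-reported category are excluded from the denominator.
#'
#' @param labels Character or factor vector of assigned ancestry labels.
#' @param sre Character vector of self-reported categories, same length;
#'   `NA` entries are dropped from the comparison.
#' @param mapping Named character vector mapping each observed category to an
#'   ancestry label; defaults to [default_sre_mapping()].
#' @return List with `concordance` (fraction of agreeing participants),
#'   `n` (participants compared) and `table` (mapped-SRE x ancestry
#'   contingency table).
#' @export
concordance <- function(labels, sre, mapping = default_sre_mapping()) {
  if (length(labels) != length(sre)) {
    stop("labels and self-reported categories must have equal length")
  }
  keep <- !is.na(sre) & !is.na(labels)
  labels <- as.character(labels)[keep]
  sre <- as.character(sre)[keep]
  if (length(labels) == 0) {
    stop("no participants with both an ancestry label and a self-reported category")
  }
  unmapped <- setdiff(unique(sre), names(mapping))
  if (length(unmapped) > 0) {
    stop("self-reported categories without a mapping: ",
         paste(unmapped, collapse = ", "))
  }
  mapped <- unname(mapping[sre])
  list(
    concordance = mean(mapped == labels),
    n = length(labels),
    table = table(mapped_sre = mapped, ancestry = labels)
  )
}
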