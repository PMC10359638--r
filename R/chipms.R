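#' Aggregate isoform-level PSM counts to proteins
#'
#' Peptide-spectrum-match counts of all isoforms of a protein are summed
#' per sample, giving one PSM value per protein per sample.
#'
#' @param psm A tibble with an `isoform` column and one numeric column per
#'   sample.
#' @param isoform_map A tibble `isoform`, `protein` covering every isoform
#'   present.
#' @return A tibble with a `protein` column and the summed sample columns.
#' @export
aggregate_psm <- function(psm, isoform_map) {
  missing <- setdiff(psm$isoform, isoform_map$isoform)
  if (length(missing)) {
    stop("unmapped isoform(s): ", paste(utils::head(missing, 5),
                                        collapse = ", "), call. = FALSE)
  }
  psm$protein <- isoform_map$protein[match(psm$isoform, isoform_map$isoform)]
  samp <- setdiff(names(psm), c("isoform", "protein"))
  if (any(unlist(psm[samp]) < 0)) stop("PSM counts must be >= 0",
                                       call. = FALSE)
  out <- dplyr::summarise(dplyr::group_by(psm, .data$protein),
                          dplyr::across(dplyr::all_of(samp), sum),
                          .groups = "drop")
  out[order(out$protein), ]
}

psm_totals <- function(psm, chip_samples, input_samples) {
  chip <- rowSums(psm[, chip_samples, drop = FALSE])
  input <- rowSums(psm[, input_samples, drop = FALSE])
  tibble::tibble(protein = psm$protein, chip = chip, input = input)
}

#' ChIP-MS candidate filter
#'
#' A protein is a candidate if its total PSM count in the ChIP samples is
#' at least `ratio` times the total in the input samples (default 2);
#' proteins seen only in ChIP (input 0, chip > 0) qualify.
#'
#' @param psm A protein-level tibble from [aggregate_psm()].
#' @param chip_samples,input_samples Column names of the ChIP and input
#'   samples.
#' @param ratio Minimum ChIP/input ratio (default 2).
#' @return The candidate rows, with `chip_total` and `input_total`
#'   columns.
#' @export
candidate_filter <- function(psm, chip_samples, input_samples, ratio = 2) {
  tot <- psm_totals(psm, chip_samples, input_samples)
  keep <- tot$chip >= ratio * tot$input & tot$chip > 0
  out <- psm[keep, ]
  out$chip_total <- tot$chip[keep]
  out$input_total <- tot$input[keep]
  out
}

#' Log2 ChIP/input enrichment per protein
#'
#' `log2((chip + pc) / (input + pc))` with a pseudocount so every protein
#' gets a finite value; monotone in the ChIP count at fixed input.
#'
#' @inheritParams candidate_filter
#' @param pseudocount Added to both totals (default 1).
#' @return A tibble `protein`, `chip_total`, `input_total`,
#'   `log2_enrichment`.
#' @export
relative_enrichment <- function(psm, chip_samples, input_samples,
                                pseudocount = 1) {
  tot <- psm_totals(psm, chip_samples, input_samples)
  tibble::tibble(
    protein = tot$protein,
    chip_total = tot$chip,
    input_total = tot$input,
    log2_enrichment = log2((tot$chip + pseudocount) /
                             (tot$input + pseudocount)))
}

#' Venn partition of candidate sets
#'
#' Counts every exclusive region of the Venn partition over two or more
#' candidate sets (all `2^k - 1` membership patterns); region counts sum
#' to the size of the union.
#'
#' @param sets A named list (>= 2) of character vectors.
#' @return A tibble `pattern` (e.g. `"A&B"`), `sets_in`, `count`.
#' @export
shared_sets <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 sets", call. = FALSE)
  nm <- names(sets)
  all_ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_ids %in% s, logical(length(all_ids)))
  if (length(all_ids) == 1) member <- matrix(member, nrow = 1)
  code <- apply(member, 1, function(r) paste(which(r), collapse = ","))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1, ,
                                                                   drop = FALSE]
  out <- lapply(seq_len(nrow(patterns)), function(i) {
    inset <- which(unlist(patterns[i, ]))
    key <- paste(inset, collapse = ",")
    tibble::tibble(pattern = paste(nm[inset], collapse = "&"),
                   sets_in = length(inset),
                   count = sum(code == key))
  })
  dplyr::bind_rows(out)
}
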