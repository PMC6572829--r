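#' Encode a PDX best-response label
#'
#' Numeric coding of RECIST-like best response: CR = 4, PR = 3, SD = 2,
#' PD = 1. A response observed as a range over time (e.g. `"PR->PD"`) is
#' encoded by its earliest response.
#'
#' @param label character vector of labels (`CR`, `PR`, `SD`, `PD`, or a
#'   range `"X->Y"`).
#' @return integer codes in 1..4.
#' @export
encode_best_response <- function(label) {
  codes <- c(CR = 4L, PR = 3L, SD = 2L, PD = 1L)
  first <- sub("\\s*(->|→).*$", "", trimws(label))
  assert_that(all(first %in% names(codes)),
              sprintf("unknown best-response label: %s",
                      paste(unique(first[!first %in% names(codes)]),
                            collapse = ", ")))
  unname(codes[first])
}

#' Combination benefit class from PDX response codes
#'
#' The change is measured against the better monotherapy:
#' `delta = combo - max(mono_a, mono_b)`. A change of +2 or more is
#' synergy, -2 or less antagonism, and +1/0/-1 additive (allowing for
#' experimental variability). An efficacy flag (combination response at
#' least PR) is carried as an annotation.
#'
#' @param combo,mono_a,mono_b integer response codes in 1..4 (vectors
#'   recycled to common length).
#' @return data.frame `delta`, `class`, `efficacy`.
#' @export
pdx_combination_class <- function(combo, mono_a, mono_b) {
  n <- max(length(combo), length(mono_a), length(mono_b))
  combo <- rep_len(as.integer(combo), n)
  mono_a <- rep_len(as.integer(mono_a), n)
  mono_b <- rep_len(as.integer(mono_b), n)
  assert_that(all(c(combo, mono_a, mono_b) %in% 1:4),
              "response codes must be in 1..4")
  delta <- combo - pmax(mono_a, mono_b)
  cls <- ifelse(delta >= 2, "synergy",
                ifelse(delta <= -2, "antagonism", "additive"))
  data.frame(delta = delta, class = cls, efficacy = combo >= 3L)
}

#' Classify a PDX cohort table
#'
#' @param pdx data.frame with `combo_id`, `model_id`, `combo`, `mono_a`,
#'   `mono_b` best-response labels (as from [simulate_pdx()]).
#' @return the input with `delta`, `class`, `efficacy` columns appended.
#' @export
classify_pdx_cohort <- function(pdx) {
  cls <- pdx_combination_class(encode_best_response(pdx$combo),
                               encode_best_response(pdx$mono_a),
                               encode_best_response(pdx$mono_b))
  cbind(pdx, cls)
}

#' Per-combination synergy-rate concordance between PDX and cell lines
#'
#' For each shared combination, pairs the fraction of PDX models classed
#' synergy with the fraction of cell lines whose synergy score is >= 20,
#' and correlates the two across combinations (Pearson).
#'
#' @param pdx_classes classified PDX table (from [classify_pdx_cohort()]).
#' @param synergy cell line synergy table (`combo_id`, `cell_id`, `score`).
#' @param threshold in vitro synergy cutoff (default 20).
#' @return list with `rates` (data.frame `combo_id`, `pdx_rate`,
#'   `cell_rate`) and `r` (Pearson correlation; `NA` with a warning when
#'   fewer than 3 combinations are shared).
#' @export
synergy_rate_concordance <- function(pdx_classes, synergy, threshold = 20) {
  shared <- intersect(unique(pdx_classes$combo_id),
                      unique(synergy$combo_id))
  rates <- do.call(rbind, lapply(shared, function(combo) {
    data.frame(
      combo_id = combo,
      pdx_rate = mean(pdx_classes$class[pdx_classes$combo_id == combo] ==
                      "synergy"),
      cell_rate = mean(synergy$score[synergy$combo_id == combo] >=
                       threshold),
      stringsAsFactors = FALSE)
  }))
  if (length(shared) < 3) {
    warning("fewer than 3 shared combinations; correlation undefined")
    return(list(rates = rates, r = NA_real_))
  }
  r <- if (stats::sd(rates$pdx_rate) == 0 || stats::sd(rates$cell_rate) == 0)
    NA_real_ else stats::cor(rates$pdx_rate, rates$cell_rate)
  list(rates = rates, r = r)
}
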