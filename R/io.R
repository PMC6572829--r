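#' Write a screen to long-format CSV
#'
#' One row per well: `combo_id, cell_line, drug_a, drug_b, dose_a, dose_b,
#' viability` (doses in uM, viability in % control; 36 rows per
#' experiment).
#'
#' @param screen list of [dose_response_matrix()] objects.
#' @param path output CSV path.
#' @param drug_map optional data.frame `combo_id`, `drug_a`, `drug_b`; when
#'   absent, drug ids are derived from the combination id.
#' @return `path`, invisibly.
#' @export
write_screen <- function(screen, path, drug_map = NULL) {
  rows <- lapply(screen, function(drm) {
    da <- db <- NA_character_
    if (!is.null(drug_map)) {
      hit <- drug_map[drug_map$combo_id == drm$combo_id, ]
      if (nrow(hit)) { da <- hit$drug_a[1]; db <- hit$drug_b[1] }
    }
    if (is.na(da)) { da <- paste0(drm$combo_id, ".A") }
    if (is.na(db)) { db <- paste0(drm$combo_id, ".B") }
    grid <- expand.grid(i = 1:6, j = 1:6)
    data.frame(combo_id = drm$combo_id, cell_line = drm$cell_id,
               drug_a = da, drug_b = db,
               dose_a = drm$doses_a[grid$i], dose_b = drm$doses_b[grid$j],
               viability = drm$viability[cbind(grid$i, grid$j)],
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format screen CSV into dose-response matrices
#'
#' Groups rows by (combination, cell line) and validates each group into a
#' 6x6 matrix: 36 unique (dose_a, dose_b) wells on a 6x6 grid whose first
#' row/column are the monotherapies. Malformed experiments are rejected
#' with the offending row numbers and the reason.
#'
#' @param path CSV with columns `combo_id`, `cell_line`, `drug_a`,
#'   `drug_b`, `dose_a`, `dose_b`, `viability`.
#' @return list with `screen` (list of [dose_response_matrix()]) and
#'   `rejected` (data.frame `combo_id`, `cell_line`, `reason`, `rows`).
#' @export
read_screen <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("combo_id", "cell_line", "drug_a", "drug_b", "dose_a",
            "dose_b", "viability")
  assert_that(all(need %in% names(df)),
              paste("screen CSV must have columns:",
                    paste(need, collapse = ", ")))
  df$.row <- seq_len(nrow(df)) + 1L  # 1-based data rows + header line
  key <- paste(df$combo_id, df$cell_line, sep = "\r")
  screen <- list(); rejected <- list()
  for (k in unique(key)) {
    sub <- df[key == k, ]
    reject <- function(reason) {
      rejected[[length(rejected) + 1L]] <<- data.frame(
        combo_id = sub$combo_id[1], cell_line = sub$cell_line[1],
        reason = reason,
        rows = paste(range(sub$.row), collapse = "-"),
        stringsAsFactors = FALSE)
    }
    if (nrow(sub) != 36) { reject("expected 36 wells"); next }
    if (anyDuplicated(sub[, c("dose_a", "dose_b")])) {
      reject("duplicated (dose_a, dose_b) well"); next
    }
    da <- sort(unique(sub$dose_a)); db <- sort(unique(sub$dose_b))
    if (length(da) != 6 || length(db) != 6 || da[1] != 0 || db[1] != 0) {
      reject("missing monotherapy row/column or malformed dose grid"); next
    }
    v <- matrix(NA_real_, 6, 6)
    v[cbind(match(sub$dose_a, da), match(sub$dose_b, db))] <- sub$viability
    if (any(is.na(v))) { reject("incomplete 6x6 grid"); next }
    drm <- tryCatch(
      dose_response_matrix(sub$combo_id[1], sub$cell_line[1], da, db, v),
      error = function(e) { reject(conditionMessage(e)); NULL })
    if (!is.null(drm)) screen[[length(screen) + 1L]] <- drm
  }
  list(screen = screen,
       rejected = if (length(rejected)) do.call(rbind, rejected)
                  else data.frame(combo_id = character(0),
                                  cell_line = character(0),
                                  reason = character(0),
                                  rows = character(0)))
}

#' Write a synergy table CSV
#' @param synergy data.frame from [score_screen()].
#' @param path output path.
#' @param seed generating seed recorded in the table.
#' @return `path`, invisibly.
#' @export
write_synergy_table <- function(synergy, path, seed = NA_integer_) {
  synergy$schema_version <- "combobench-1"
  synergy$seed <- seed
  utils::write.csv(synergy, path, row.names = FALSE)
  invisible(path)
}

#' Read a prediction file CSV
#'
#' Expected columns: `cell_line`, `combination_id`, `prediction`.
#'
#' @param path CSV path.
#' @return data.frame `combo_id`, `cell_id`, `prediction`.
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_line", "combination_id", "prediction")
  assert_that(all(need %in% names(df)),
              paste("prediction CSV must have columns:",
                    paste(need, collapse = ", ")))
  data.frame(combo_id = df$combination_id, cell_id = df$cell_line,
             prediction = df$prediction, stringsAsFactors = FALSE)
}

#' Write a prediction file CSV
#' @param pred data.frame `combo_id`, `cell_id`, `prediction`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  utils::write.csv(
    data.frame(cell_line = pred$cell_id, combination_id = pred$combo_id,
               prediction = pred$prediction),
    path, row.names = FALSE)
  invisible(path)
}
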