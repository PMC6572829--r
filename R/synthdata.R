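#' Generate a synthetic cell line panel with a binary event matrix
#'
#' Creates `n_cells` cell lines spread over the given tissue labels and a
#' genes x cells binary event matrix (BEM) whose entries are independent
#' Bernoulli(`event_prob`). Genes that would come out all-zero are given one
#' event in a deterministically chosen cell so that every gene row is usable
#' as a candidate biomarker.
#'
#' @param n_cells number of cell lines (>= 2).
#' @param n_genes number of BEM genes.
#' @param tissues character vector of tissue labels to cycle over.
#' @param event_prob per-entry alteration probability, in (0, 1).
#' @param seed integer seed.
#' @return list of class `cell_line_panel` with `cell_ids`, `tissue`
#'   (named by cell), and `bem` (genes x cells 0/1 matrix).
#' @export
make_panel <- function(n_cells, n_genes, tissues = c("breast", "lung",
                       "bladder", "GI"), event_prob = 0.2, seed = 1L) {
  assert_that(n_cells >= 2, "n_cells must be >= 2")
  assert_that(n_genes >= 1, "n_genes must be >= 1")
  assert_that(event_prob > 0 && event_prob < 1,
              "event_prob must be in (0, 1)")
  with_seed(substream_seed(seed, "panel"), {
    cell_ids <- sprintf("CL%03d", seq_len(n_cells))
    tissue <- stats::setNames(
      rep_len(tissues, n_cells)[sample.int(n_cells)], cell_ids)
    gene_ids <- sprintf("G%03d", seq_len(n_genes))
    bem <- matrix(stats::rbinom(n_genes * n_cells, 1L, event_prob),
                  nrow = n_genes, ncol = n_cells,
                  dimnames = list(gene_ids, cell_ids))
    zero <- which(rowSums(bem) == 0)
    for (g in zero) bem[g, sample.int(n_cells, 1L)] <- 1L
    structure(list(cell_ids = cell_ids, tissue = tissue, bem = bem),
              class = "cell_line_panel")
  })
}

#' Generate a synthetic drug library
#'
#' Each drug is annotated with one putative target gene (drawn from the
#' panel's BEM genes) and one pathway group; pathway groups partition the
#' drugs.
#'
#' @param n_drugs number of drugs.
#' @param genes character vector of candidate target genes.
#' @param n_pathways number of pathway groups.
#' @param seed integer seed.
#' @return data.frame `drug_id`, `target_gene`, `pathway_group`.
#' @export
make_drug_library <- function(n_drugs, genes, n_pathways = 4L, seed = 1L) {
  assert_that(n_drugs >= 1, "n_drugs must be >= 1")
  assert_that(length(genes) >= 1, "need at least one candidate target gene")
  with_seed(substream_seed(seed, "drugs"), {
    data.frame(
      drug_id = sprintf("D%02d", seq_len(n_drugs)),
      target_gene = sample(genes, n_drugs, replace = TRUE),
      pathway_group = paste0("PW", rep_len(seq_len(n_pathways), n_drugs)),
      stringsAsFactors = FALSE)
  })
}

#' Default 6-point dose series
#'
#' A 5-point geometric series (default ratio x4, spanning ~2.4 log10 units)
#' plus the zero dose, highest dose `top` uM.
#'
#' @param top highest dose (uM).
#' @param ratio dilution ratio between successive doses.
#' @return length-6 numeric vector starting at 0.
#' @export
dose_series <- function(top = 10, ratio = 4) {
  assert_that(top > 0 && ratio > 1, "top must be > 0 and ratio > 1")
  c(0, top / ratio^(4:0))
}

# Smooth separable Gaussian bump over the 5x5 positive log-dose grid,
# scaled so its area-normalised log-space integral equals delta; by
# construction the scorer's target equals delta exactly. The bump is broad
# (sd = half the log-dose range) so that realistic amplitudes are not
# truncated by the 0% viability floor.
synergy_bump <- function(delta, doses_a, doses_b) {
  pa <- doses_a[doses_a > 0]; pb <- doses_b[doses_b > 0]
  la <- log10(pa); lb <- log10(pb)
  ga <- exp(-((la - mean(range(la)))^2) / (2 * (diff(range(la)) / 2)^2))
  gb <- exp(-((lb - mean(range(lb)))^2) / (2 * (diff(range(lb)) / 2)^2))
  B <- outer(ga, gb)
  if (delta == 0) return(B * 0)
  s <- synergy_score(B, doses_a, doses_b, cap = Inf)
  B * (delta / s)
}

random_true_curve <- function(top_dose) {
  # e0 pinned at 100 so the untreated control is exact pre-noise; potency
  # sits in the upper half of the dose range so mid-grid viability stays
  # clear of the 0% floor even under an injected synergy bump
  hill_curve(e0 = 100,
             e_inf = stats::runif(1, 25, 50),
             ec50 = exp(stats::runif(1, log(top_dose / 8),
                                     log(top_dose / 2))),
             h = stats::runif(1, 0.8, 3))
}

# Monotherapy resistance in biomarker carriers: shallower maximal effect and
# reduced potency. The combination restores sensitivity via the synergy bump,
# which is what links monotherapy-resistance markers to combination synergy.
resist_curve <- function(curve, shift = 25, potency_factor = 2) {
  hill_curve(e0 = curve$e0,
             e_inf = min(curve$e_inf + shift, 75),
             ec50 = curve$ec50 * potency_factor,
             h = curve$h)
}

#' Simulate a dose-matrix combination screen with known ground truth
#'
#' For every (combination, cell line) pair in the design, draws two Hill
#' monotherapy curves (baseline pinned at 100% control), builds the exact
#' Loewe-additive 6x6 surface, subtracts a smooth synergy bump whose
#' log-space area-normalised integral equals the pair's ground-truth
#' amplitude delta, adds truncated Gaussian noise on % viability and clips
#' to \[0, 120\].
#'
#' Delta is drawn per experiment: if the combination is coupled to a
#' biomarker gene, the probability that the experiment falls in the synergy
#' regime follows a logistic link on the cell's event indicator;
#' otherwise delta comes from the background (additive) regime.
#'
#' @param panel a [make_panel()] result.
#' @param drugs a [make_drug_library()] result.
#' @param design data.frame with columns `combo_id`, `cell_id`, `drug_a`,
#'   `drug_b` (one row per experiment).
#' @param delta_synergy mean bump amplitude in the synergy regime
#'   (score units; default 35).
#' @param delta_sd spread of delta around its regime mean (default 8).
#' @param background_sd spread of the additive-regime delta about 0
#'   (default 5).
#' @param noise_sd Gaussian viability noise sd (% control; default 0).
#' @param coupling `NULL` for no biomarker coupling, otherwise a list with
#'   `genes` (named character: combo_id -> gene) and logistic link
#'   intercept/slope `b0`, `b1` (defaults -3, 6: carriers are very likely,
#'   non-carriers very unlikely, to land in the synergy regime). Carriers
#'   additionally get monotherapy-resistant curves for both drugs
#'   (`resistance_shift`, default 25 % viability added to `e_inf`, and
#'   doubled ec50), so the coupled gene is a monotherapy resistance marker
#'   whose carriers regain sensitivity under the combination.
#' @param top_dose highest dose of the series (uM).
#' @param seed integer seed.
#' @return list with `screen` (list of [dose_response_matrix()]) and
#'   `truth` (data.frame: `combo_id`, `cell_id`, `delta`, `noise_sd`,
#'   `biomarker_gene`, `event`, and the true curve parameters).
#' @export
simulate_screen <- function(panel, drugs, design, delta_synergy = 35,
                            delta_sd = 8, background_sd = 5, noise_sd = 0,
                            coupling = NULL, top_dose = 10, seed = 1L) {
  assert_that(nrow(design) > 0, "design must be non-empty")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(all(c("combo_id", "cell_id") %in% names(design)),
              "design needs combo_id and cell_id columns")
  doses <- dose_series(top = top_dose)
  with_seed(substream_seed(seed, "screen"), {
    screen <- vector("list", nrow(design))
    truth <- vector("list", nrow(design))
    for (k in seq_len(nrow(design))) {
      combo <- design$combo_id[k]; cell <- design$cell_id[k]
      gene <- NA_character_; event <- NA_integer_
      if (!is.null(coupling) && combo %in% names(coupling$genes)) {
        gene <- coupling$genes[[combo]]
        event <- panel$bem[gene, cell]
        b0 <- coupling$b0 %||% -3; b1 <- coupling$b1 %||% 6
        p_syn <- stats::plogis(b0 + b1 * event)
        in_syn <- stats::rbinom(1L, 1L, p_syn) == 1L
        delta <- if (in_syn) stats::rnorm(1, delta_synergy, delta_sd)
                 else stats::rnorm(1, 0, background_sd)
      } else {
        delta <- stats::rnorm(1, 0, background_sd)
      }
      ca <- random_true_curve(top_dose)
      cb <- random_true_curve(top_dose)
      if (!is.na(event) && event == 1L) {
        shift <- coupling$resistance_shift %||% 25
        ca <- resist_curve(ca, shift)
        cb <- resist_curve(cb, shift)
      }
      surf <- loewe_surface(ca, cb, doses, doses)
      bump <- synergy_bump(delta, doses, doses)
      v <- surf
      v[2:6, 2:6] <- v[2:6, 2:6] - bump
      if (noise_sd > 0) v <- v + stats::rnorm(36, 0, noise_sd)
      v <- pmin(pmax(v, 0), 120)
      attr(v, "fallback") <- NULL
      screen[[k]] <- dose_response_matrix(combo, cell, doses, doses, v)
      truth[[k]] <- data.frame(
        combo_id = combo, cell_id = cell, delta = delta,
        noise_sd = noise_sd, biomarker_gene = gene, event = event,
        e0_a = ca$e0, einf_a = ca$e_inf, ec50_a = ca$ec50, h_a = ca$h,
        e0_b = cb$e0, einf_b = cb$e_inf, ec50_b = cb$ec50, h_b = cb$h,
        stringsAsFactors = FALSE)
    }
    list(screen = screen, truth = do.call(rbind, truth))
  })
}

#' Simulate teams predicting a synergy table
#'
#' Continuous predictions are built as correlated copies of the truth:
#' for target correlation `rho`, prediction = `rho * z + sqrt(1 - rho^2) * e`
#' on the standardised scale (independent noise per team, so teams are
#' conditionally independent given the truth), mapped back to the truth's
#' mean and sd. The binary variant thresholds a noisy copy of the truth at
#' the synergy cutoff (20).
#'
#' @param truth data.frame with `combo_id`, `cell_id`, `score`.
#' @param n_teams number of teams (>= 1).
#' @param skill numeric vector (recycled to `n_teams`) of target Pearson
#'   correlations in \[-1, 1\].
#' @param binarize if TRUE also return thresholded binary predictions.
#' @param binarize_threshold score cutoff for the binary variant.
#' @param seed integer seed.
#' @return list of prediction data.frames (one per team) with columns
#'   `combo_id`, `cell_id`, `prediction` and, when `binarize`,
#'   `prediction_binary`; names are team ids.
#' @export
simulate_teams <- function(truth, n_teams, skill = 0.5, binarize = TRUE,
                           binarize_threshold = 20, seed = 1L) {
  assert_that(n_teams >= 1, "n_teams must be >= 1")
  skill <- rep_len(skill, n_teams)
  assert_that(all(skill >= -1 & skill <= 1), "skill must be in [-1, 1]")
  y <- truth$score
  sdy <- stats::sd(y)
  z <- (y - mean(y)) / if (sdy > 0) sdy else 1
  with_seed(substream_seed(seed, "teams"), {
    out <- lapply(seq_len(n_teams), function(t) {
      rho <- skill[t]
      e <- stats::rnorm(length(y))
      zp <- rho * z + sqrt(max(0, 1 - rho^2)) * e
      pred <- mean(y) + zp * (if (sdy > 0) sdy else 1)
      df <- data.frame(combo_id = truth$combo_id, cell_id = truth$cell_id,
                       prediction = pred, stringsAsFactors = FALSE)
      if (binarize)
        df$prediction_binary <- as.integer(pred >= binarize_threshold)
      df
    })
    names(out) <- sprintf("team%02d", seq_len(n_teams))
    out
  })
}

#' Simulate conditionally independent binary classifier teams
#'
#' Given true binary labels and per-team balanced accuracies, each team
#' predicts by independently flipping the true label with error rate
#' `1 - bac` in both classes (sensitivity = specificity = bac), the
#' canonical conditional-independence model assumed by the spectral
#' meta-learner.
#'
#' @param labels true labels in \{0, 1\}.
#' @param bac per-team balanced accuracy in \[0, 1\].
#' @param seed integer seed.
#' @return teams x experiments matrix of 0/1 predictions (rownames are
#'   team ids).
#' @export
simulate_classifier_teams <- function(labels, bac, seed = 1L) {
  assert_that(all(labels %in% c(0, 1)), "labels must be 0/1")
  assert_that(all(bac >= 0 & bac <= 1), "bac must be in [0, 1]")
  n <- length(labels)
  with_seed(substream_seed(seed, "classifier_teams"), {
    preds <- t(vapply(bac, function(b) {
      keep <- stats::rbinom(n, 1L, b)
      ifelse(keep == 1L, labels, 1L - labels)
    }, integer(n)))
    rownames(preds) <- sprintf("team%02d", seq_along(bac))
    preds
  })
}

#' Split a screen design into challenge sets
#'
#' SC1: within each combination, cells are split train/leaderboard/
#' validation in proportions 3/6, 1/6, 2/6 (leaderboard count is
#' `floor(n/6)`, validation `floor(n/3)`, remainder to train); combinations
#' measured in fewer than 6 cells are excluded with a warning. SC2: the
#' combinations themselves are split into two equal disjoint halves
#' (leaderboard / validation), odd combination going to the leaderboard.
#'
#' @param design data.frame with `combo_id`, `cell_id`.
#' @param mode `"SC1"` or `"SC2"`.
#' @param seed integer seed.
#' @return for SC1 the design with an extra `set` column
#'   (`train`/`leaderboard`/`validation`); for SC2 a data.frame
#'   `combo_id`, `set` (`leaderboard`/`validation`).
#' @export
make_splits <- function(design, mode = c("SC1", "SC2"), seed = 1L) {
  mode <- match.arg(mode)
  with_seed(substream_seed(seed, paste0("splits_", mode)), {
    if (mode == "SC1") {
      out <- NULL
      for (combo in unique(design$combo_id)) {
        cells <- sort(unique(design$cell_id[design$combo_id == combo]))
        n <- length(cells)
        if (n < 6) {
          warning(sprintf(
            "combination %s has %d < 6 cells under SC1; excluded", combo, n))
          next
        }
        n_lead <- floor(n / 6); n_val <- floor(n / 3)
        n_train <- n - n_lead - n_val
        perm <- sample(cells)
        set <- rep(c("train", "leaderboard", "validation"),
                   c(n_train, n_lead, n_val))
        out <- rbind(out, data.frame(combo_id = combo, cell_id = perm,
                                     set = set, stringsAsFactors = FALSE))
      }
      assert_that(!is.null(out), "no combination has >= 6 cells")
      out
    } else {
      combos <- sort(unique(design$combo_id))
      perm <- sample(combos)
      half <- ceiling(length(combos) / 2)
      data.frame(combo_id = perm,
                 set = rep(c("leaderboard", "validation"),
                           c(half, length(combos) - half)),
                 stringsAsFactors = FALSE)
    }
  })
}

#' Simulate a PDX cohort with best-response records
#'
#' For each drug pair and model, draws monotherapy best responses from a
#' background distribution over \{PD, SD, PR, CR\} and a combination
#' response whose probability of exceeding the better monotherapy by >= 2
#' levels is elevated in biomarker-positive models when coupling is on.
#'
#' @param drug_pairs data.frame with `combo_id`, `drug_a`, `drug_b`.
#' @param n_models number of PDX models per pair (>= 1).
#' @param coupling `NULL`, or list with `prevalence` (biomarker carrier
#'   rate, default 0.3), `p_benefit_pos`, `p_benefit_neg` (probability a
#'   carrier / non-carrier model's combination jumps >= +2; defaults 0.6 /
#'   0.1).
#' @param seed integer seed.
#' @return data.frame with one row per (pair, model): `combo_id`,
#'   `model_id`, `event`, `mono_a`, `mono_b`, `combo` (response labels).
#' @export
simulate_pdx <- function(drug_pairs, n_models, coupling = NULL, seed = 1L) {
  assert_that(n_models >= 1, "n_models must be >= 1")
  labels <- c("PD", "SD", "PR", "CR")
  mono_probs <- c(0.55, 0.25, 0.15, 0.05)
  prev <- (coupling$prevalence %||% 0.3)
  p_pos <- (coupling$p_benefit_pos %||% 0.6)
  p_neg <- (coupling$p_benefit_neg %||% 0.1)
  with_seed(substream_seed(seed, "pdx"), {
    rows <- list()
    for (k in seq_len(nrow(drug_pairs))) {
      for (m in seq_len(n_models)) {
        event <- if (is.null(coupling)) 0L else stats::rbinom(1L, 1L, prev)
        mono_a <- sample(4L, 1L, prob = mono_probs)
        mono_b <- sample(4L, 1L, prob = mono_probs)
        best <- max(mono_a, mono_b)
        p_jump <- if (is.null(coupling)) p_neg
                  else if (event == 1L) p_pos else p_neg
        combo <- if (stats::runif(1) < p_jump && best <= 2L) {
          best + 2L
        } else {
          # additive-ish: stay near the better monotherapy
          min(max(best + sample(c(-1L, 0L, 1L), 1L,
                                prob = c(0.2, 0.6, 0.2)), 1L), 4L)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          combo_id = drug_pairs$combo_id[k],
          model_id = sprintf("PDX%04d", (k - 1L) * n_models + m),
          event = event,
          mono_a = labels[mono_a], mono_b = labels[mono_b],
          combo = labels[combo], stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Build a dense or sparse screen design
#'
#' Assigns each combination a random subset of cells (all cells when
#' `cells_per_combo` is `NULL`), pairing drugs round-robin.
#'
#' @param panel a [make_panel()] result.
#' @param drugs a [make_drug_library()] result.
#' @param n_combos number of drug combinations.
#' @param cells_per_combo cells measured per combination (`NULL` = all).
#' @param seed integer seed.
#' @return design data.frame `combo_id`, `cell_id`, `drug_a`, `drug_b`.
#' @export
make_design <- function(panel, drugs, n_combos, cells_per_combo = NULL,
                        seed = 1L) {
  assert_that(n_combos >= 1, "n_combos must be >= 1")
  nd <- nrow(drugs)
  assert_that(nd >= 2, "need at least two drugs")
  with_seed(substream_seed(seed, "design"), {
    pairs <- t(vapply(seq_len(n_combos), function(i) {
      sample(drugs$drug_id, 2L)
    }, character(2)))
    rows <- lapply(seq_len(n_combos), function(i) {
      cells <- if (is.null(cells_per_combo)) panel$cell_ids
               else sample(panel$cell_ids,
                           min(cells_per_combo, length(panel$cell_ids)))
      data.frame(combo_id = sprintf("C%03d", i), cell_id = cells,
                 drug_a = pairs[i, 1], drug_b = pairs[i, 2],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
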