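#' Extend a binary event matrix with copy-number calls
#'
#' A gene is altered in a cell if it is deleted (copy number 0), amplified
#' (more than 7 copies) or mutated in any sense.
#'
#' @param mutations genes x cells matrix of mutation indicators (any
#'   positive entry counts as mutated).
#' @param copy_numbers genes x cells matrix of non-negative integer copy
#'   numbers, same dimensions and dimnames.
#' @return genes x cells 0/1 integer matrix (the extended BEM) with a
#'   `provenance` attribute (genes x cells character:
#'   `"mutation"`, `"deletion"`, `"amplification"`, `"none"`;
#'   mutation wins when several apply).
#' @export
extend_bem <- function(mutations, copy_numbers) {
  mutations <- as.matrix(mutations)
  copy_numbers <- as.matrix(copy_numbers)
  assert_that(all(dim(mutations) == dim(copy_numbers)),
              "mutations and copy_numbers must have identical dimensions")
  assert_that(all(copy_numbers >= 0), "copy numbers must be non-negative")
  assert_that(all(copy_numbers == round(copy_numbers)),
              "copy numbers must be integers")
  mut <- mutations > 0
  del <- copy_numbers == 0
  amp <- copy_numbers > 7
  bem <- (mut | del | amp) * 1L
  prov <- matrix("none", nrow(bem), ncol(bem), dimnames = dimnames(mutations))
  prov[amp] <- "amplification"
  prov[del] <- "deletion"
  prov[mut] <- "mutation"
  dimnames(bem) <- dimnames(mutations)
  attr(bem, "provenance") <- prov
  bem
}

#' Monotherapy sensitivity from a fitted Hill curve
#'
#' Defined as one minus the normalised area under the fitted viability
#' curve over the tested log10-dose range (viability scaled to \[0, 1\]);
#' higher values mean more sensitive.
#'
#' @param curve a [hill_curve()].
#' @param doses the tested dose vector (positive doses used).
#' @param n integration grid size.
#' @return sensitivity in \[0, 1\].
#' @export
monotherapy_sensitivity <- function(curve, doses, n = 101L) {
  pos <- doses[doses > 0]
  assert_that(length(pos) >= 2, "need >= 2 positive doses")
  lg <- seq(log10(min(pos)), log10(max(pos)), length.out = n)
  v <- hill_response(curve, 10^lg) / 100
  auc <- sum((v[-1] + v[-n]) / 2 * diff(lg)) / diff(range(lg))
  1 - max(min(auc, 1), 0)
}

#' Monotherapy biomarker associations
#'
#' For each (drug, gene) pair, splits the drug's per-cell sensitivity
#' values by the gene's mutational status and tests the separation with a
#' two-sided Wilcoxon rank-sum test (exact for small untied groups).
#' Direction is `resistance` when the mutant median sensitivity is below
#' the wild-type median, `sensitivity` when above, `NA` when equal.
#' Pairs with fewer than `min_group` cells in either group are skipped.
#'
#' @param mono_response data.frame `drug_id`, `cell_id`, `sensitivity`.
#' @param bem genes x cells 0/1 matrix.
#' @param min_group minimum cells per group (default 3).
#' @return data.frame `drug_id`, `gene`, `p`, `direction`, `n_mut`, `n_wt`.
#' @export
monotherapy_association <- function(mono_response, bem, min_group = 3L) {
  assert_that(all(c("drug_id", "cell_id", "sensitivity") %in%
                  names(mono_response)),
              "mono_response needs drug_id, cell_id, sensitivity")
  out <- list()
  for (drug in unique(mono_response$drug_id)) {
    sub <- mono_response[mono_response$drug_id == drug, ]
    cells <- intersect(sub$cell_id, colnames(bem))
    sub <- sub[match(cells, sub$cell_id), ]
    for (gene in rownames(bem)) {
      mut <- cells[bem[gene, cells] == 1]
      wt <- setdiff(cells, mut)
      if (length(mut) < min_group || length(wt) < min_group) next
      xm <- sub$sensitivity[match(mut, sub$cell_id)]
      xw <- sub$sensitivity[match(wt, sub$cell_id)]
      p <- suppressWarnings(
        stats::wilcox.test(xm, xw, alternative = "two.sided")$p.value)
      mm <- stats::median(xm); mw <- stats::median(xw)
      dir <- if (mm < mw) "resistance" else if (mm > mw) "sensitivity"
             else NA_character_
      out[[length(out) + 1L]] <- data.frame(
        drug_id = drug, gene = gene, p = p, direction = dir,
        n_mut = length(mut), n_wt = length(wt), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(drug_id = character(0), gene = character(0),
                      p = numeric(0), direction = character(0),
                      n_mut = integer(0), n_wt = integer(0)))
  do.call(rbind, out)
}

# Linked-experiment indicator at a -log10(p) threshold: a (combo, cell)
# experiment is linked when either of its drugs has a resistance-direction
# association at or above the threshold and the cell carries the event.
linked_at <- function(synergy, assocs, bem, threshold) {
  vapply(seq_len(nrow(synergy)), function(k) {
    drugs <- c(synergy$drug_a[k], synergy$drug_b[k])
    cand <- assocs[assocs$drug_id %in% drugs &
                   assocs$direction == "resistance" &
                   -log10(assocs$p) >= threshold, , drop = FALSE]
    if (nrow(cand) == 0) return(FALSE)
    any(bem[cand$gene, synergy$cell_id[k]] == 1)
  }, logical(1))
}

#' Synergy enrichment across monotherapy-marker stringency
#'
#' Sweeps a -log10(p) threshold grid (step 0.1) over the
#' resistance-direction monotherapy associations. At each threshold an
#' experiment is linked when one of its drugs has a qualifying resistance
#' marker that the cell carries; the curve reports the fraction of
#' experiments selected and the percentage of linked experiments that are
#' synergistic (score >= 20). The whole computation is bootstrapped on
#' random 80% subsets of the experiments (5 replicates by default).
#'
#' @param assocs [monotherapy_association()] output.
#' @param synergy data.frame `combo_id`, `cell_id`, `drug_a`, `drug_b`,
#'   `score`.
#' @param bem genes x cells 0/1 matrix.
#' @param step threshold grid step (default 0.1).
#' @param boot `c(replicates, fraction)` for the bootstrap (default 5, 0.8).
#' @param seed integer seed.
#' @return list of class `enrichment_curve`: `curve` (data.frame
#'   `threshold`, `n_linked`, `selected_fraction`, `pct_synergistic`),
#'   `boot` (list of replicate curves), and `r` (Pearson correlation of
#'   `pct_synergistic` vs `selected_fraction` over defined grid points).
#' @export
synergy_enrichment <- function(assocs, synergy, bem, step = 0.1,
                               boot = c(5, 0.8), seed = 1L) {
  assert_that(nrow(assocs) > 0, "assocs must be non-empty")
  res <- assocs[assocs$direction %in% "resistance", , drop = FALSE]
  assert_that(nrow(res) > 0, "no resistance-direction association")
  tmax <- max(-log10(res$p))
  grid <- seq(0, max(tmax, step), by = step)

  one_curve <- function(syn) {
    n_tot <- nrow(syn)
    rows <- lapply(grid, function(t) {
      linked <- linked_at(syn, res, bem, t)
      n <- sum(linked)
      data.frame(threshold = t, n_linked = n,
                 selected_fraction = n / n_tot,
                 pct_synergistic = if (n == 0) NA_real_
                                   else 100 * mean(syn$score[linked] >= 20))
    })
    do.call(rbind, rows)
  }

  curve <- one_curve(synergy)
  boots <- list()
  with_seed(substream_seed(seed, "enrichment_boot"), {
    for (b in seq_len(boot[1])) {
      idx <- sample.int(nrow(synergy), round(boot[2] * nrow(synergy)))
      boots[[b]] <- one_curve(synergy[idx, , drop = FALSE])
    }
  })
  ok <- !is.na(curve$pct_synergistic) & curve$n_linked > 0
  r <- if (sum(ok) >= 3 && stats::sd(curve$selected_fraction[ok]) > 0 &&
           stats::sd(curve$pct_synergistic[ok]) > 0) {
    stats::cor(curve$selected_fraction[ok], curve$pct_synergistic[ok])
  } else NA_real_
  structure(list(curve = curve, boot = boots, r = r),
            class = "enrichment_curve")
}

#' Tissue-corrected ANOVA for synergy biomarkers
#'
#' For each candidate (gene, combination) pair, fits
#' `synergy ~ tissue + event` over that combination's cell lines and takes
#' the sequential F-test p-value of the event term after tissue; with a
#' single tissue the model reduces to a two-group comparison (warned).
#' Benjamini-Hochberg is applied across all candidates jointly. Effect
#' size is mean(mutant) - mean(wild-type) synergy.
#'
#' @param synergy data.frame `combo_id`, `cell_id`, `score`.
#' @param bem genes x cells 0/1 matrix.
#' @param tissues named character vector (cell id -> tissue).
#' @param candidates data.frame `gene`, `combo_id`.
#' @param min_group minimum mutant and wild-type cells (default 2).
#' @return data.frame `gene`, `combo_id`, `effect_size`, `p`, `q`,
#'   `n_mut`, `n_wt`.
#' @export
synergy_biomarker_anova <- function(synergy, bem, tissues, candidates,
                                    min_group = 2L) {
  assert_that(nrow(candidates) > 0, "candidates must be non-empty")
  rows <- list()
  for (k in seq_len(nrow(candidates))) {
    gene <- candidates$gene[k]; combo <- candidates$combo_id[k]
    sub <- synergy[synergy$combo_id == combo, ]
    cells <- intersect(sub$cell_id, colnames(bem))
    sub <- sub[match(cells, sub$cell_id), ]
    ev <- bem[gene, cells]
    if (sum(ev == 1) < min_group || sum(ev == 0) < min_group) next
    tis <- factor(tissues[cells])
    df <- data.frame(y = sub$score, tissue = tis, event = ev)
    if (nlevels(droplevels(tis)) < 2) {
      warning(sprintf(
        "candidate %s/%s: all cells one tissue; two-group comparison",
        gene, combo))
      fit <- stats::lm(y ~ event, data = df)
      an <- stats::anova(fit)
      p <- an["event", "Pr(>F)"]
    } else {
      fit <- stats::lm(y ~ tissue + event, data = df)
      an <- stats::anova(fit)
      p <- an["event", "Pr(>F)"]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene = gene, combo_id = combo,
      effect_size = mean(df$y[ev == 1]) - mean(df$y[ev == 0]),
      p = p, n_mut = sum(ev == 1), n_wt = sum(ev == 0),
      stringsAsFactors = FALSE)
  }
  assert_that(length(rows) > 0, "no candidate had enough cells per group")
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[, c("gene", "combo_id", "effect_size", "p", "q", "n_mut", "n_wt")]
}

#' Directionality validation on an independent synergy table
#'
#' Recomputes each discovery association's effect size (mean mutant minus
#' wild-type synergy) on an independent table and reports the fraction with
#' concordant sign. Candidates absent from the independent table (or with
#' too few cells per group) are excluded from the denominator.
#'
#' @param discovery [synergy_biomarker_anova()] output.
#' @param synergy_indep independent synergy table
#'   (`combo_id`, `cell_id`, `score`).
#' @param bem_indep genes x cells 0/1 matrix for the independent panel.
#' @param min_group minimum cells per group (default 2).
#' @return list with `concordance` (fraction in \[0, 1\]) and `detail`
#'   data.frame (`gene`, `combo_id`, `effect_discovery`, `effect_indep`,
#'   `concordant`).
#' @export
validate_directionality <- function(discovery, synergy_indep, bem_indep,
                                    min_group = 2L) {
  rows <- list()
  for (k in seq_len(nrow(discovery))) {
    gene <- discovery$gene[k]; combo <- discovery$combo_id[k]
    if (!gene %in% rownames(bem_indep)) next
    sub <- synergy_indep[synergy_indep$combo_id == combo, ]
    cells <- intersect(sub$cell_id, colnames(bem_indep))
    if (length(cells) == 0) next
    sub <- sub[match(cells, sub$cell_id), ]
    ev <- bem_indep[gene, cells]
    if (sum(ev == 1) < min_group || sum(ev == 0) < min_group) next
    eff <- mean(sub$score[ev == 1]) - mean(sub$score[ev == 0])
    rows[[length(rows) + 1L]] <- data.frame(
      gene = gene, combo_id = combo,
      effect_discovery = discovery$effect_size[k],
      effect_indep = eff,
      concordant = sign(eff) == sign(discovery$effect_size[k]),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(list(concordance = NA_real_,
                detail = data.frame(gene = character(0))))
  detail <- do.call(rbind, rows)
  list(concordance = mean(detail$concordant), detail = detail)
}
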