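#' @title Profactual / counterfactual explanations
#' @description
#' Interrogates a trained classifier around a baseline molecule: the
#' structural neighborhood is sampled by random robust-string edits of the
#' baseline (1-3 token edits per sample), keeping only pi-filter-passing,
#' non-baseline structures. Samples are labeled by the model and split into
#' profactuals (same predicted label as the baseline) and counterfactuals
#' (flipped label); each side keeps the k most similar members by Tanimoto
#' similarity on the classifier's 1024-bit fingerprints.
#' @name explainability
NULL

#' Sample the structural neighborhood of a baseline
#'
#' @param baseline_smiles baseline molecule
#' @param n_samples distinct neighbors wanted (full-scale setting 15000;
#'   desk-scale work uses far fewer)
#' @param cfg a [pi_filter_config()] enforced on every sample
#' @param attempt_factor raw-edit budget as a multiple of `n_samples`
#' @return character vector of canonical SMILES (baseline excluded); may
#'   fall short of `n_samples` when the budget is exhausted
#' @export
sample_neighborhood <- function(baseline_smiles, n_samples = 1000L,
                                cfg = pi_filter_config(),
                                attempt_factor = 10L) {
  stopifnot(n_samples >= 1)
  base <- smiles_to_genome(baseline_smiles)
  seen <- new.env(parent = emptyenv())
  out <- character(0)
  attempts <- 0L
  budget <- attempt_factor * n_samples
  while (length(out) < n_samples && attempts < budget) {
    chunk <- min(budget - attempts, max(128L, 2L * (n_samples - length(out))))
    attempts <- attempts + chunk
    smi <- vapply(seq_len(chunk), function(k) {
      toks <- mutate_tokens(base$tokens, sample.int(3L, 1L))
      s <- rts_to_smiles(toks)
      if (is.na(s)) NA_character_ else s
    }, character(1))
    smi <- smi[!is.na(smi)]
    if (length(smi) == 0) next
    d <- chem_describe(smi, forbidden = cfg$forbidden_substructures)
    pass <- pi_filter_table(d, cfg)$passed &
      d$canonical != base$canonical & !is.na(d$canonical)
    for (s in unique(d$canonical[which(pass)])) {
      if (length(out) >= n_samples) break
      if (is.null(seen[[s]])) {
        seen[[s]] <- TRUE
        out <- c(out, s)
      }
    }
  }
  out
}

#' Build an explanation set
#'
#' @param baseline_smiles baseline molecule (canonicalized internally)
#' @param samples character vector of neighbor SMILES (e.g. from
#'   [sample_neighborhood()])
#' @param model an `invest_classifier`
#' @param k members per side (default 9)
#' @return an `explanation_set`: baseline info plus `profactuals` and
#'   `counterfactuals` data.frames (canonical, similarity, predicted_label),
#'   each at most k rows ordered by descending similarity
#' @export
build_explanations <- function(baseline_smiles, samples, model, k = 9L) {
  baseline <- chem_canonical(baseline_smiles)
  samples <- setdiff(unique(samples), baseline)
  radius <- if (is.function(model)) 2L else model$radius
  nbits <- if (is.function(model)) 1024L else model$nbits
  base_fp <- chem_fingerprints(baseline, radius = radius, nbits = nbits)[[1]]
  base_label <- ifelse(predict_good(model, baseline) > 0.5, "good", "bad")
  if (length(samples) == 0) {
    empty <- data.frame(canonical = character(), similarity = numeric(),
                        predicted_label = character(), stringsAsFactors = FALSE)
    return(structure(list(baseline = baseline, baseline_label = base_label,
                          profactuals = empty, counterfactuals = empty, k = k),
                     class = "explanation_set"))
  }
  fps <- chem_fingerprints(samples, radius = radius, nbits = nbits)
  sim <- tanimoto(base_fp, fps)
  lab <- ifelse(predict_good(model, samples) > 0.5, "good", "bad")
  df <- data.frame(canonical = samples, similarity = sim,
                   predicted_label = lab, stringsAsFactors = FALSE)
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  take <- function(side) {
    side <- side[order(-side$similarity, side$canonical), , drop = FALSE]
    side[seq_len(min(k, nrow(side))), , drop = FALSE]
  }
  pro <- take(df[df$predicted_label == base_label, , drop = FALSE])
  con <- take(df[df$predicted_label != base_label, , drop = FALSE])
  if (nrow(con) == 0) warning("no counterfactuals among the samples")
  structure(list(baseline = baseline, baseline_label = base_label,
                 profactuals = pro, counterfactuals = con, k = k),
            class = "explanation_set")
}

#' @export
print.explanation_set <- function(x, ...) {
  cat("<explanation_set> baseline ", x$baseline, " (", x$baseline_label, ")\n",
      "  ", nrow(x$profactuals), " profactuals, ",
      nrow(x$counterfactuals), " counterfactuals (k = ", x$k, ")\n", sep = "")
  invisible(x)
}

#' Explain a baseline end to end
#'
#' Samples the neighborhood and builds the 9+9 explanation set.
#'
#' @param baseline_smiles baseline molecule
#' @param model an `invest_classifier`
#' @param n_samples neighborhood size
#' @param k members per side
#' @param cfg a [pi_filter_config()]
#' @return an `explanation_set`
#' @export
explain_molecule <- function(baseline_smiles, model, n_samples = 1000L,
                             k = 9L, cfg = pi_filter_config()) {
  samples <- sample_neighborhood(baseline_smiles, n_samples, cfg = cfg)
  build_explanations(baseline_smiles, samples, model, k = k)
}
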