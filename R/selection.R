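# Exploratory single-predictor sweep over window lengths and features,
# window and feature selection, and the forward model build-up.

.OUTCOMES <- c("agitation", "motor", "verbal")

# context terms usable in `data` (factors need >= 2 levels after filtering)
.context_terms <- function(data, terms = c("time_group", "maj_room_group")) {
  terms[vapply(terms, function(tm)
    tm %in% names(data) && nlevels(droplevels(factor(data[[tm]]))) >= 2L,
    logical(1))]
}

.cell_formula <- function(outcome, zcol, data, group = "patient_id") {
  ctx <- .context_terms(data, "time_group")
  as.formula(paste(outcome, "~", paste(c(zcol, ctx), collapse = " + "),
                   "+ (1 |", group, ")"))
}

#' Exploratory single-predictor sweep across window lengths
#'
#' For every window length, standardized feature (5 per modality) and outcome
#' (overall, motor, verbal agitation), fits the exploratory model
#' `outcome ~ z_feature + time_group + (1 | patient_id)` and records the
#' feature coefficient, its SE and Wald p-value. Non-converged cells are kept
#' as rows flagged `converged = FALSE` with `NA` estimates, never imputed.
#'
#' @param x a `ward_dataset` (features are extracted at `lengths`) or a
#'   feature table from [extract_features()] (its lengths are used).
#' @param lengths window lengths in minutes (ignored when `x` is a feature
#'   table).
#' @param buffer buffer in minutes.
#' @param nAGQ quadrature nodes passed to [fit_glmm()].
#' @return `data.table` of class `beta_grid` keyed by (length, modality,
#'   feature, outcome) with `beta`, `se`, `p`, `n`, `converged`.
#' @export
sweep_windows <- function(x, lengths = seq(3, 30, by = 3), buffer = 12,
                          nAGQ = 25L) {
  feats <- if (inherits(x, "ward_dataset"))
    extract_features(x, lengths = lengths, buffer = buffer)$features
  else if (is.list(x) && "features" %in% names(x)) x$features
  else as.data.table(x)
  lens <- sort(unique(feats$length_min))
  grid <- CJ(length_min = lens, modality = .MODALITIES,
             feature = .FEATURES, outcome = .OUTCOMES, sorted = FALSE)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i]
    zcol <- paste0("z_", g$modality, "_", g$feature)
    d <- feats[feats$length_min == g$length_min & feats$pass &
                 !is.na(feats[[zcol]])]
    row <- data.table(g, beta = NA_real_, se = NA_real_, p = NA_real_,
                      n = nrow(d), converged = FALSE)
    fit <- tryCatch(
      fit_glmm(.cell_formula(g$outcome, zcol, d), d, nAGQ = nAGQ),
      error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      row$beta <- unname(fit$beta[zcol])
      row$se <- unname(fit$se[zcol])
      row$p <- unname(fit$p_value[zcol])
      row$converged <- TRUE
    }
    res[[i]] <- row
  }
  out <- rbindlist(res)
  class(out) <- c("beta_grid", class(out))
  out
}

#' Select the analysis window length from the sweep
#'
#' Operationalizes "the window with the maximum amount of information",
#' combining magnitude and significance: each (modality, feature, outcome)
#' cell votes for the length at which it attains its across-length maximum
#' absolute coefficient, provided it is significant there, and the vote is
#' weighted by the cell's absolute Wald statistic (so a handful of strongly
#' informative cells outweighs a bloc of marginal, mutually correlated
#' ones). The length with the highest total wins; longer lengths win ties
#' (more context in the window). If no cell votes anywhere the configured
#' default is returned with a warning.
#'
#' @param grid a `beta_grid` from [sweep_windows()].
#' @param alpha significance level for a cell to vote (default 0.05).
#' @param default fallback length when no votes are cast.
#' @return Selected window length in minutes (with a `scores` attribute).
#' @export
select_window <- function(grid, alpha = 0.05, default = 21) {
  g <- as.data.table(grid)
  lens <- sort(unique(g$length_min))
  conv <- g[, .(frac = mean(converged)), by = length_min]
  if (any(conv$frac < 0.8))
    warning("lengths with < 80% converged cells: ",
            paste(conv$length_min[conv$frac < 0.8], collapse = ", "))
  gc_ <- g[converged == TRUE & !is.na(beta)]
  gc_[, max_abs := max(abs(beta)), by = .(modality, feature, outcome)]
  votes <- gc_[abs(abs(beta) - max_abs) < 1e-12 & p < alpha]
  scores <- setNames(rep(0, length(lens)), lens)
  if (nrow(votes)) {
    tab <- votes[, .(w = sum(abs(beta / se))), by = length_min]
    scores[as.character(tab$length_min)] <- tab$w
  }
  if (all(scores == 0)) {
    warning("no significant maxima anywhere; returning default length ",
            default)
    return(structure(default, scores = scores))
  }
  best <- max(scores)
  chosen <- max(as.numeric(names(scores)[scores == best]))  # tie: longer
  structure(chosen, scores = scores)
}

#' Select the most informative feature per modality and outcome
#'
#' At the chosen window length, the feature with the largest absolute
#' coefficient is selected per (outcome, modality); ties are broken by the
#' fixed feature order (min, max, mean, median, sd). A whole modality is
#' dropped from the subsequent build-up -- for all outcomes -- when none of
#' its features is significantly associated with any outcome at this length
#' (the fate of temperature in practice).
#'
#' @param grid a `beta_grid`.
#' @param length window length in minutes present in the grid.
#' @param alpha significance level (default 0.05).
#' @return List of class `ward_selection`: `window`, `table` (per outcome x
#'   modality: feature, beta, p, significant, selected), `dropped`.
#' @export
select_features <- function(grid, length, alpha = 0.05) {
  g <- as.data.table(grid)[length_min == length & converged == TRUE &
                             !is.na(beta)]
  if (!nrow(g)) stop("grid has no converged cells at length ", length)
  g[, feature := factor(feature, levels = .FEATURES)]
  setorder(g, outcome, modality, feature)
  sel <- g[, .SD[which.max(abs(beta) - as.integer(feature) * 1e-12)],
           by = .(outcome, modality)]
  sig_any <- g[, .(any_sig = any(p < alpha)), by = modality]
  dropped <- sig_any$modality[!sig_any$any_sig]
  sel[, significant := p < alpha]
  sel[, selected := !(modality %in% dropped)]
  structure(list(window = length, table = sel[], dropped = dropped),
            class = "ward_selection")
}

#' @export
print.ward_selection <- function(x, ...) {
  cat("Feature selection at the", x$window, "minute window\n")
  print(x$table[, .(outcome, modality, feature, beta = round(beta, 3),
                    p = signif(p, 2), significant, selected)],
        row.names = FALSE)
  if (length(x$dropped))
    cat("dropped modalities (no significant feature for any outcome):",
        paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Forward model build-up for one outcome
#'
#' Reproduces the staged model sequence: model 0 is the patient-intercept
#' null, models 1-2 add the contextual covariates (time group, majority room
#' group), models 3-4 add the selected sound and light features separately on
#' top of the context, model 5 both, and models 6-9 the interactions of each
#' modality with time and room. Each addition is gated by a chi-square
#' likelihood-ratio test; the contextual covariates are retained regardless
#' of their test (domain knowledge: sundowning, location confounding), the
#' environmental and interaction terms only when their test is significant.
#' All models in the sequence are fitted on the identical listwise-complete
#' row set so every comparison is valid.
#'
#' @param features feature table at the chosen length (quality-passing rows
#'   are selected internally).
#' @param selection a `ward_selection` from [select_features()].
#' @param outcome one of `"agitation"`, `"motor"`, `"verbal"`.
#' @param alpha LRT significance level (default 0.05).
#' @param nAGQ quadrature nodes.
#' @return Object of class `ward_buildup`: `fits` (models "0".."9" and
#'   `final`), `anova_table` (model, variable added, comparison, p, kept),
#'   `kept_terms`, `outcome`.
#' @export
forward_build <- function(features, selection, outcome, alpha = 0.05,
                          nAGQ = 25L) {
  stopifnot(inherits(selection, "ward_selection"),
            outcome %in% .OUTCOMES)
  feats <- as.data.table(features)
  if ("length_min" %in% names(feats) &&
      selection$window %in% feats$length_min)
    feats <- feats[length_min == selection$window]
  tab <- selection$table
  zc <- function(mod) {
    r <- tab[tab$outcome == outcome & tab$modality == mod & tab$selected, ]
    if (nrow(r)) paste0("z_", mod, "_", r$feature[1]) else NULL
  }
  z_sound <- zc("sound"); z_light <- zc("light")
  used <- c(z_sound, z_light)
  d <- feats[feats$pass == TRUE]
  if (length(used))
    d <- d[complete.cases(as.data.frame(d)[, used, drop = FALSE])]
  d <- droplevels(as.data.frame(d))
  ctx <- .context_terms(d)

  fml <- function(terms) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    as.formula(paste(outcome, "~", rhs, "+ (1 | patient_id)"))
  }
  specs <- list(
    "0" = character(0),
    "1" = intersect("time_group", ctx),
    "2" = ctx,
    "3" = if (!is.null(z_sound)) c(ctx, z_sound),
    "4" = if (!is.null(z_light)) c(ctx, z_light),
    "5" = if (!is.null(z_sound) && !is.null(z_light))
      c(ctx, z_sound, z_light),
    "6" = if (!is.null(z_sound) && "time_group" %in% ctx)
      c(ctx, z_sound, paste0(z_sound, ":time_group")),
    "7" = if (!is.null(z_sound) && "maj_room_group" %in% ctx)
      c(ctx, z_sound, paste0(z_sound, ":maj_room_group")),
    "8" = if (!is.null(z_light) && "time_group" %in% ctx)
      c(ctx, z_light, paste0(z_light, ":time_group")),
    "9" = if (!is.null(z_light) && "maj_room_group" %in% ctx)
      c(ctx, z_light, paste0(z_light, ":maj_room_group"))
  )
  fits <- lapply(names(specs), function(id) {
    if (is.null(specs[[id]]) && id != "0") return(NULL)
    tryCatch(fit_glmm(fml(specs[[id]]), d, nAGQ = nAGQ),
             error = function(e) {
               warning("model ", id, " failed: ", conditionMessage(e))
               NULL
             })
  })
  names(fits) <- names(specs)

  comparisons <- list(
    c("1", "0", "+ time_groups"),
    c("2", "1", "+ maj_room"),
    c("3", "2", "+ sound parameter"),
    c("4", "2", "+ light parameter (to 2)"),
    c("5", "2", "+ both light and sound (to 2)"),
    c("5", "3", "+ both light and sound (to 3)"),
    c("5", "4", "+ both light and sound (to 4)"),
    c("6", "3", "+ sound*time"),
    c("7", "3", "+ sound*room"),
    c("8", "4", "+ light*time"),
    c("9", "4", "+ light*room")
  )
  rows <- lapply(comparisons, function(cp) {
    fo <- fits[[cp[1]]]; ne <- fits[[cp[2]]]
    out <- data.table(model = cp[1], variable_added = cp[3],
                      vs = cp[2], delta_df = NA_integer_, p = NA_real_)
    if (!is.null(fo) && !is.null(ne)) {
      lr <- tryCatch(lrt(ne, fo, alpha = alpha), error = function(e) NULL)
      if (!is.null(lr)) {
        out$delta_df <- lr$delta_df
        out$p <- lr$p_value
      }
    }
    out
  })
  atab <- rbindlist(rows)

  pval <- function(model) atab$p[match(model, atab$model)]
  kept <- ctx  # context kept on domain knowledge regardless of the LRT
  sound_kept <- !is.null(z_sound) && isTRUE(pval("3") < alpha)
  light_kept <- !is.null(z_light) && isTRUE(pval("4") < alpha)
  if (sound_kept) kept <- c(kept, z_sound)
  if (light_kept) kept <- c(kept, z_light)
  if (sound_kept && "time_group" %in% ctx && isTRUE(pval("6") < alpha))
    kept <- c(kept, paste0(z_sound, ":time_group"))
  if (sound_kept && "maj_room_group" %in% ctx && isTRUE(pval("7") < alpha))
    kept <- c(kept, paste0(z_sound, ":maj_room_group"))
  if (light_kept && "time_group" %in% ctx && isTRUE(pval("8") < alpha))
    kept <- c(kept, paste0(z_light, ":time_group"))
  if (light_kept && "maj_room_group" %in% ctx && isTRUE(pval("9") < alpha))
    kept <- c(kept, paste0(z_light, ":maj_room_group"))
  atab[, kept := vapply(seq_len(.N), function(i) {
    term <- switch(atab$model[i], "3" = z_sound, "4" = z_light,
                   "6" = , "7" = , "8" = , "9" = {
                     k <- atab$model[i]
                     sp <- specs[[k]]
                     if (is.null(sp)) NULL else tail(sp, 1)
                   }, NULL)
    if (is.null(term)) TRUE else term %in% kept
  }, logical(1))]
  final <- tryCatch(fit_glmm(fml(kept), d, nAGQ = nAGQ),
                    error = function(e) NULL)
  fits$final <- final
  structure(list(outcome = outcome, fits = fits, anova_table = atab[],
                 kept_terms = kept, n_obs = nrow(d), alpha = alpha),
            class = "ward_buildup")
}

#' @export
print.ward_buildup <- function(x, ...) {
  cat("Forward model build-up for outcome:", x$outcome,
      sprintf("(n = %d)\n", x$n_obs))
  at <- copy(x$anova_table)
  at[, p := signif(p, 3)]
  print(at, row.names = FALSE)
  cat("kept terms:", if (length(x$kept_terms))
    paste(x$kept_terms, collapse = ", ") else "(intercept only)", "\n")
  invisible(x)
}
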