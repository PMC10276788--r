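## Linear binding models: dG_pred = alpha dE_vdw + beta dE_coul +
## gamma dG_solv (+ delta). Four variants: full or vdW-only regressors,
## with or without the intercept delta. All fits are ordinary least
## squares via stats::lm; no iterative optimization, no randomness.

.VARIANTS <- c("full_int", "full_noint", "vdwonly_int", "vdwonly_noint")

.variant_terms <- function(variant) {
  variant <- match.arg(variant, .VARIANTS)
  list(
    regressors = if (startsWith(variant, "full"))
      c("dE_vdw", "dE_coul", "dG_solv") else "dE_vdw",
    intercept = endsWith(variant, "_int"),
    variant = variant
  )
}

#' Goodness-of-fit statistics
#'
#' `rmse = sqrt(mean((pred - obs)^2))`; `r2 = 1 - SS_res / SS_tot` with
#' `SS_tot` taken about the mean of the observations for every model
#' variant, including no-intercept fits (one R^2 convention throughout).
#' Zero-variance observations make R^2 undefined (`NA` with a warning);
#' the RMSE is still returned.
#'
#' @param pred,obs numeric vectors of equal length (kcal/mol).
#' @return list with `r2`, `rmse`, `n`.
#' @export
fit_statistics <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(obs) >= 2)
  rmse <- sqrt(mean((pred - obs)^2))
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) {
    warning("zero-variance observations: R^2 undefined")
    r2 <- NA_real_
  } else r2 <- 1 - sum((obs - pred)^2) / ss_tot
  list(r2 = r2, rmse = rmse, n = length(obs))
}

#' Fit a LIECE linear binding model
#'
#' Ordinary least squares of `dg_exp` on the variant's energy terms.
#' `*_noint` variants constrain the intercept to zero (regression through
#' the origin).
#'
#' @param rows energy table (see [read_energy_table()]) with columns
#'   `dE_vdw`, `dE_coul`, `dG_solv`, `dg_exp`.
#' @param variant one of `"full_int"`, `"full_noint"`, `"vdwonly_int"`,
#'   `"vdwonly_noint"`.
#' @return object of class `liece_model`: coefficients (`alpha`, `beta`,
#'   `gamma`, `delta` as applicable), `variant`, `n_train`, `fit`
#'   (from [fit_statistics()]) and `loo` (`NULL` until [loo_cv()]).
#' @export
fit_liece <- function(rows, variant = "full_int") {
  vt <- .variant_terms(variant)
  rows <- as.data.frame(rows)
  p <- length(vt$regressors) + vt$intercept
  if (nrow(rows) < p + 1)
    stop("need at least ", p + 1, " ligands to fit ", vt$variant,
         " (", nrow(rows), " given)")
  fml <- stats::as.formula(paste(
    "dg_exp ~", paste(vt$regressors, collapse = " + "),
    if (!vt$intercept) "- 1" else ""
  ))
  fit <- stats::lm(fml, data = rows)
  if (fit$rank < p) {
    al <- stats::alias(fit)$Complete
    stop("rank-deficient design; collinear column(s): ",
         paste(rownames(al), collapse = ", "))
  }
  cf <- stats::coef(fit)
  coefs <- c(alpha = unname(cf["dE_vdw"]))
  if (startsWith(vt$variant, "full"))
    coefs <- c(coefs, beta = unname(cf["dE_coul"]),
               gamma = unname(cf["dG_solv"]))
  if (vt$intercept)
    coefs <- c(coefs, delta = unname(cf["(Intercept)"]))
  structure(list(
    coefficients = coefs, variant = vt$variant, n_train = nrow(rows),
    fit = fit_statistics(stats::fitted(fit), rows$dg_exp),
    loo = NULL,
    training_ids = rows$ligand_id
  ), class = "liece_model")
}

#' @export
print.liece_model <- function(x, ...) {
  cat(sprintf("<liece_model> %s, n = %d\n", x$variant, x$n_train))
  print(round(x$coefficients, 4))
  cat(sprintf("  R^2 = %.3f, RMSE = %.3f kcal/mol\n", x$fit$r2, x$fit$rmse))
  if (!is.null(x$loo))
    cat(sprintf("  loo: <ddG> = %.3f, coef std: %s\n", x$loo$mean_ddg,
                paste(sprintf("%s=%.3g", names(x$loo$coef_std),
                              x$loo$coef_std), collapse = ", ")))
  invisible(x)
}

#' Predict binding free energies from a fitted model
#'
#' Dot product of the variant's coefficients with the energy terms, plus
#' the intercept when present.
#'
#' @param model a `liece_model`.
#' @param terms named numeric vector (`dE_vdw`, `dE_coul`, `dG_solv`), or
#'   a data.frame of energy rows (vectorized).
#' @return predicted dG in kcal/mol.
#' @export
predict_dg <- function(model, terms) {
  stopifnot(inherits(model, "liece_model"))
  cf <- model$coefficients
  if (is.data.frame(terms)) {
    out <- cf["alpha"] * terms$dE_vdw
    if ("beta" %in% names(cf))
      out <- out + cf["beta"] * terms$dE_coul + cf["gamma"] * terms$dG_solv
  } else {
    out <- cf["alpha"] * terms[["dE_vdw"]]
    if ("beta" %in% names(cf))
      out <- out + cf["beta"] * terms[["dE_coul"]] +
        cf["gamma"] * terms[["dG_solv"]]
  }
  if ("delta" %in% names(cf)) out <- out + cf["delta"]
  unname(out)
}

#' Leave-one-out stability analysis of a LIECE model
#'
#' Refits the model `n` times, each time omitting one ligand, and reports
#' the spread of the coefficients and the mean gap between full-model and
#' leave-one-out predictions.
#'
#' `ddg_mode = "left_out"` (default) averages, over folds, the signed
#' difference `full-model prediction - loo-model prediction` for the
#' left-out ligand only; `"all"` averages the difference over every ligand
#' for every fold.
#'
#' @param rows energy table used for the fit.
#' @param variant model variant.
#' @param full_model optional prefitted full model (refitted if `NULL`).
#' @param ddg_mode `"left_out"` or `"all"`.
#' @param coef_norm `"population"` (divide by n; default) or `"sample"`
#'   standard deviation of the coefficients across refits.
#' @return list of class `liece_loo` with `coef_std`, `mean_ddg` and
#'   `per_fold` (left-out id, coefficients, loo prediction, full
#'   prediction).
#' @export
loo_cv <- function(rows, variant = "full_int", full_model = NULL,
                   ddg_mode = c("left_out", "all"),
                   coef_norm = c("population", "sample")) {
  ddg_mode <- match.arg(ddg_mode)
  coef_norm <- match.arg(coef_norm)
  vt <- .variant_terms(variant)
  rows <- as.data.frame(rows)
  n <- nrow(rows)
  p <- length(vt$regressors) + vt$intercept
  if (n < p + 2)
    stop("leave-one-out needs at least ", p + 2, " ligands (", n, " given)")
  if (is.null(full_model)) full_model <- fit_liece(rows, variant)
  full_pred <- predict_dg(full_model, rows)

  coef_mat <- matrix(NA_real_, n, length(full_model$coefficients),
                     dimnames = list(NULL, names(full_model$coefficients)))
  loo_pred_left <- numeric(n)
  ddg_all <- numeric(0)
  for (i in seq_len(n)) {
    m_i <- tryCatch(fit_liece(rows[-i, , drop = FALSE], variant),
                    error = function(e)
                      stop("leave-one-out fold ", i, " (ligand ",
                           rows$ligand_id[i], ") failed: ",
                           conditionMessage(e)))
    coef_mat[i, ] <- m_i$coefficients
    loo_pred_left[i] <- predict_dg(m_i, rows[i, , drop = FALSE])
    if (ddg_mode == "all")
      ddg_all <- c(ddg_all, full_pred - predict_dg(m_i, rows))
  }
  sd_pop <- function(v) sqrt(mean((v - mean(v))^2))
  coef_std <- apply(coef_mat, 2,
                    if (coef_norm == "population") sd_pop else stats::sd)
  mean_ddg <- if (ddg_mode == "left_out") mean(full_pred - loo_pred_left)
              else mean(ddg_all)
  structure(list(
    coef_std = coef_std, mean_ddg = mean_ddg, ddg_mode = ddg_mode,
    per_fold = data.frame(left_out = rows$ligand_id,
                          coef_mat, loo_pred = loo_pred_left,
                          full_pred = full_pred)
  ), class = "liece_loo")
}

#' Evaluate a fitted model on an external ligand set
#'
#' @param model a `liece_model` (trained on a disjoint set).
#' @param rows energy table of the external set (with `dg_exp`).
#' @return [fit_statistics()] of the external predictions.
#' @export
evaluate_external <- function(model, rows) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0) stop("empty external set")
  fit_statistics(predict_dg(model, rows), rows$dg_exp)
}

#' Fit every (dataset x program x receptor x variant) combination
#'
#' Groups an energy table by its three grouping columns and fits each of
#' the requested variants per group, with leave-one-out statistics. This is
#' the bulk-refit used to tabulate model quality across conditions.
#'
#' @param rows energy table.
#' @param variants character vector of model variants.
#' @param loo run [loo_cv()] per model (skipped for groups too small)?
#' @return data.frame with one row per fitted model: grouping columns,
#'   variant, n, coefficients, `r2`, `rmse`, `mean_ddg` and coefficient
#'   standard deviations; the fitted models in `attr(, "models")`.
#' @export
fit_liece_models <- function(rows, variants = .VARIANTS, loo = TRUE) {
  rows <- as.data.frame(rows)
  key <- interaction(rows$dataset_label, rows$docking_program,
                     rows$receptor_model, drop = TRUE, sep = "|")
  res <- NULL
  models <- list()
  for (g in levels(key)) {
    sub <- rows[key == g, , drop = FALSE]
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    for (v in variants) {
      vt <- .variant_terms(v)
      p <- length(vt$regressors) + vt$intercept
      if (nrow(sub) < p + 2) next
      m <- fit_liece(sub, v)
      if (loo) m$loo <- loo_cv(sub, v, full_model = m)
      models[[paste(g, v, sep = "|")]] <- m
      cf <- m$coefficients
      res <- rbind(res, data.frame(
        dataset_label = parts[1], docking_program = parts[2],
        receptor_model = parts[3], variant = v, n = m$n_train,
        alpha = cf["alpha"],
        beta = if ("beta" %in% names(cf)) cf["beta"] else NA_real_,
        gamma = if ("gamma" %in% names(cf)) cf["gamma"] else NA_real_,
        delta = if ("delta" %in% names(cf)) cf["delta"] else NA_real_,
        r2 = m$fit$r2, rmse = m$fit$rmse,
        mean_ddg = if (loo) m$loo$mean_ddg else NA_real_,
        alpha_std = if (loo) m$loo$coef_std["alpha"] else NA_real_,
        row.names = NULL))
    }
  }
  attr(res, "models") <- models
  res
}
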