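# GBLUP / GFBLUP mixed models: fixed-effect design, average-information REML
# with EM fallback for the variance components, and BLUP genomic breeding
# values for reference and masked validation animals.
#
# Model: y = X b + sum_f g_f + e,  g_f ~ N(0, G_f sigma_f^2),  e ~ N(0, I sigma_e^2).
# Traditional GBLUP uses one whole-genome G; GFBLUP uses one G per feature
# chromosome plus a rest-of-genome G.

#' Wilmink lactation-curve covariate
#'
#' `exp(-0.05 * DIM)`, the exponential term of the Wilmink adjustment that
#' captures the steep phenotype change in early lactation. The exponent
#' -0.05 per day is fixed.
#'
#' @param dim days in milk, >= 0
#' @return numeric covariate values
#' @export
wilmink_covariate <- function(dim) {
  if (any(dim < 0)) gfb_stop("DIM must be nonnegative", "domain_error")
  exp(-0.05 * dim)
}

#' Build the fixed-effect design matrix
#'
#' Columns: intercept (overall mean), treatment-coded parity and herd classes
#' (first level as reference), linear DIM, and the Wilmink covariate
#' `exp(-0.05 * DIM)`. Factors with a single observed level are omitted;
#' rank-deficient columns are dropped with a warning.
#'
#' @param phenos phenotype data.frame with columns `animal_id`, `herd`,
#'   `parity`, `dim`
#' @return object of class `fixed_design`: list(X, ids)
#' @export
build_fixed_design <- function(phenos) {
  need <- c("animal_id", "herd", "parity", "dim")
  if (!all(need %in% names(phenos))) {
    gfb_stop(paste0("phenotype table needs columns: ", paste(need, collapse = ", ")),
             "structure_error")
  }
  if (anyNA(phenos$herd) || anyNA(phenos$parity) || anyNA(phenos$dim)) {
    gfb_stop("herd, parity and dim must be non-missing for modeled rows",
             "structure_error")
  }
  df <- data.frame(
    parity = factor(phenos$parity),
    herd = factor(phenos$herd),
    dim = phenos$dim,
    wilmink = wilmink_covariate(phenos$dim)
  )
  terms <- c(
    if (nlevels(df$parity) > 1L) "parity",
    if (nlevels(df$herd) > 1L) "herd",
    "dim", "wilmink"
  )
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(fml, df)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop_cols <- colnames(X)[qr_x$pivot[-seq_len(qr_x$rank)]]
    warning(paste0("dropping rank-deficient fixed-effect column(s): ",
                   paste(drop_cols, collapse = ", ")))
    X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
  }
  structure(list(X = X, ids = phenos$animal_id), class = "fixed_design")
}

#' @export
print.fixed_design <- function(x, ...) {
  cat("fixed_design:", nrow(x$X), "records x", ncol(x$X), "columns (",
      paste(colnames(x$X), collapse = ", "), ")\n")
  invisible(x)
}

# normalise the grms argument: named list of `grm` objects or plain matrices,
# each subset/reordered to `ids`
align_grms <- function(grms, ids) {
  if (inherits(grms, "grm")) grms <- list(genomic = grms)
  if (inherits(grms, "grm_set")) grms <- grm_components(grms)
  if (is.null(names(grms)) || any(names(grms) == "")) {
    names(grms) <- paste0("g", seq_along(grms))
  }
  lapply(grms, function(g) {
    if (inherits(g, "grm")) {
      i <- match(ids, g$ids)
      if (anyNA(i)) gfb_stop("GRM does not cover all required ids", "alignment_error")
      g$G[i, i, drop = FALSE]
    } else {
      m <- as.matrix(g)
      if (!is.null(rownames(m))) {
        i <- match(ids, rownames(m))
        if (anyNA(i)) gfb_stop("GRM does not cover all required ids", "alignment_error")
        m[i, i, drop = FALSE]
      } else {
        if (nrow(m) != length(ids)) gfb_stop("unnamed GRM has wrong dimension", "alignment_error")
        m
      }
    }
  })
}

# P v for P = Vinv - Vinv X (X'Vinv X)^-1 X'Vinv, given T = Vinv X and
# B = (X'Vinv X)^-1
apply_P <- function(Vinv, T_mat, B, v) {
  Vinv %*% v - T_mat %*% (B %*% crossprod(T_mat, v))
}

reml_loglik_parts <- function(theta, Gs, y, X) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (i in seq_along(Gs)) V <- V + theta[i] * Gs[[i]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vinv <- chol2inv(ch)
  T_mat <- Vinv %*% X
  XtVX <- crossprod(X, T_mat)
  chx <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(chx)) return(NULL)
  B <- chol2inv(chx)
  Py <- as.numeric(apply_P(Vinv, T_mat, B, y))
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                  sum(y * Py))
  list(Vinv = Vinv, T_mat = T_mat, B = B, Py = Py, loglik = ll)
}

#' Estimate variance components by average-information REML
#'
#' Fits `y = X b + sum_f g_f + e` with `g_f ~ N(0, G_f sigma_f^2)` and
#' `e ~ N(0, I sigma_e^2)` by restricted maximum likelihood. Updates use the
#' average-information algorithm; when an AI step would leave the parameter
#' space or reduce the restricted log-likelihood, an EM step is taken
#' instead. Components hitting the lower boundary are pinned at
#' `1e-8 * var(y)` and flagged.
#'
#' @param y named numeric response vector (names = animal ids)
#' @param X a [build_fixed_design()] result or a plain design matrix aligned
#'   to `y`
#' @param grms a `grm`, a `grm_set`, or a (named) list of `grm` objects or
#'   matrices, each covering the ids of `y`
#' @param tol_loglik convergence threshold on the restricted log-likelihood
#'   change (default 1e-6)
#' @param tol_param convergence threshold on the maximum relative parameter
#'   change (default 1e-5)
#' @param max_iter iteration cap (default 200); non-convergence is an error
#'   carrying the iteration trace
#' @param verbose print per-iteration estimates
#' @return object of class `variance_components`: list(components (named),
#'   residual, loglik, iterations, converged, boundary (named logical),
#'   trace (data.frame), beta (GLS fixed-effect solutions at convergence))
#' @export
reml_fit <- function(y, X, grms, tol_loglik = 1e-6, tol_param = 1e-5,
                     max_iter = 200L, verbose = FALSE) {
  if (inherits(X, "fixed_design")) {
    ids <- X$ids
    X <- X$X
  } else {
    ids <- names(y)
  }
  if (is.null(ids)) gfb_stop("y must carry ids (names or via fixed_design)", "alignment_error")
  if (!is.null(names(y)) && !identical(names(y), ids)) {
    y <- y[ids]
    if (anyNA(y)) gfb_stop("y does not cover all design ids", "alignment_error")
  }
  y <- as.numeric(y)
  n <- length(y)
  Gs <- align_grms(grms, ids)
  c_g <- length(Gs)
  if (n <= ncol(X) + c_g) gfb_stop("too few records for the model", "structure_error")

  vy <- stats::var(y)
  floor_v <- 1e-8 * vy
  theta <- c(rep(vy / 2 / c_g, c_g), vy / 2)
  comp_names <- c(names(Gs), "residual")
  names(theta) <- comp_names

  parts <- reml_loglik_parts(theta, Gs, y, X)
  if (is.null(parts)) gfb_stop("singular V at the starting values; try a ridge", "numeric_error")
  trace <- data.frame(iteration = 0L, loglik = parts$loglik,
                      t(theta), check.names = FALSE)
  converged <- FALSE
  iter <- 0L
  pinned <- rep(FALSE, c_g + 1L)

  while (iter < max_iter) {
    iter <- iter + 1L
    Vinv <- parts$Vinv; T_mat <- parts$T_mat; B <- parts$B; Py <- parts$Py
    # w_i = G_i P y (identity for the residual)
    w <- vector("list", c_g + 1L)
    trPG <- numeric(c_g + 1L)
    yPGPy <- numeric(c_g + 1L)
    for (i in seq_len(c_g)) {
      w[[i]] <- as.numeric(Gs[[i]] %*% Py)
      GT <- Gs[[i]] %*% T_mat
      trPG[i] <- sum(Vinv * Gs[[i]]) - sum(B * crossprod(T_mat, GT))
      yPGPy[i] <- sum(Py * w[[i]])
    }
    w[[c_g + 1L]] <- Py
    trPG[c_g + 1L] <- sum(diag(Vinv)) - sum(B * crossprod(T_mat))
    yPGPy[c_g + 1L] <- sum(Py * Py)
    grad <- -0.5 * (trPG - yPGPy)

    Pw <- lapply(w, function(v) as.numeric(apply_P(Vinv, T_mat, B, v)))
    AI <- matrix(0, c_g + 1L, c_g + 1L)
    for (i in seq_len(c_g + 1L)) {
      for (j in i:(c_g + 1L)) {
        AI[i, j] <- AI[j, i] <- 0.5 * sum(w[[i]] * Pw[[j]])
      }
    }
    delta <- tryCatch(solve(AI, grad), error = function(e) {
      solve(AI + diag(1e-8 * max(diag(AI)), nrow(AI)), grad)
    })

    new_parts <- NULL
    used_em <- FALSE
    # AI proposal with out-of-bounds components clamped to the floor;
    # step-halve on likelihood decrease
    step <- 1
    for (h in 1:6) {
      cand <- pmax(theta + step * delta, floor_v)
      p_try <- reml_loglik_parts(cand, Gs, y, X)
      if (!is.null(p_try) && p_try$loglik >= parts$loglik - 1e-10) {
        proposal <- cand; new_parts <- p_try
        break
      }
      step <- step / 2
    }
    if (is.null(new_parts)) {
      # EM update: sigma_new = sigma + sigma^2/n (y'PGPy - tr(PG))
      used_em <- TRUE
      proposal <- theta + theta^2 / n * (yPGPy - trPG)
      proposal <- pmax(proposal, floor_v)
      new_parts <- reml_loglik_parts(proposal, Gs, y, X)
      if (is.null(new_parts)) {
        gfb_stop("REML update produced a singular system; consider a ridge on G",
                 "numeric_error", trace = trace)
      }
    }
    pinned <- proposal <= floor_v * (1 + 1e-12)
    pinned[c_g + 1L] <- FALSE
    proposal[pinned] <- floor_v

    dll <- abs(new_parts$loglik - parts$loglik)
    rel <- max(abs(proposal - theta) / (abs(theta) + 1e-12))
    theta <- proposal
    parts <- new_parts
    trace <- rbind(trace, data.frame(iteration = iter, loglik = parts$loglik,
                                     t(theta), check.names = FALSE))
    if (verbose) {
      message(sprintf("iter %d: loglik %.6f [%s]%s", iter, parts$loglik,
                      paste(sprintf("%.4g", theta), collapse = ", "),
                      if (used_em) " (EM)" else ""))
    }
    if (dll < tol_loglik && rel < tol_param) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    gfb_stop(paste0("REML did not converge in ", max_iter, " iterations"),
             "convergence_error", trace = trace)
  }
  beta <- as.numeric(parts$B %*% crossprod(parts$T_mat, y))
  names(beta) <- colnames(X)
  structure(list(
    components = theta[seq_len(c_g)],
    residual = theta[[c_g + 1L]],
    loglik = parts$loglik,
    iterations = iter,
    converged = converged,
    boundary = stats::setNames(pinned[seq_len(c_g)], names(Gs)),
    trace = trace,
    beta = beta
  ), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("variance_components (REML,", x$iterations, "iterations):\n")
  comps <- c(x$components, residual = x$residual)
  for (nm in names(comps)) {
    cat(sprintf("  %-10s %.6g%s\n", nm, comps[[nm]],
                if (nm %in% names(x$boundary) && x$boundary[[nm]]) "  [boundary]" else ""))
  }
  cat(sprintf("  log-REML  %.4f\n", x$loglik))
  invisible(x)
}

#' Construct a variance_components object from known values
#'
#' For fixing components externally, e.g. to verify the GFBLUP-to-GBLUP
#' reduction with `sigma_f^2 = sigma_a^2 s_f / s_total`.
#'
#' @param components named numeric vector of genetic variances
#' @param residual residual variance (> 0)
#' @return a `variance_components` object
#' @export
variance_components <- function(components, residual) {
  stopifnot(all(components >= 0), residual >= 0)
  structure(list(components = components, residual = residual,
                 loglik = NA_real_, iterations = 0L, converged = NA,
                 boundary = stats::setNames(rep(FALSE, length(components)),
                                            names(components)),
                 trace = NULL, beta = NULL),
            class = "variance_components")
}

#' Solve the mixed model for genomic breeding values
#'
#' Computes GLS fixed-effect solutions and BLUP genomic breeding values at
#' the supplied variance components. Individuals in `masked_ids` keep their
#' rows in every GRM but their phenotypes are excluded from the data vector,
#' so their GBVs are pure genomic predictions, as in cross-validation of
#' unphenotyped candidates. Predictions use `g_f = sigma_f^2 G_f[, obs] V_obs^{-1} (y_obs -
#' X_obs b)`, the direct solution of Henderson's equations that avoids
#' inverting possibly singular GRMs.
#'
#' @param y named numeric phenotypes for all individuals (masked included)
#' @param X a [build_fixed_design()] or matrix aligned to `y`
#' @param grms as in [reml_fit()]
#' @param vc a `variance_components` object
#' @param masked_ids ids whose phenotypes are withheld
#' @return object of class `model_fit`: list(beta, gbv (matrix, one column
#'   per component), gbv_total, fixed_fitted (all ids), fitted and residuals
#'   (observed ids), vc, ids, masked_ids)
#' @export
blup_solve <- function(y, X, grms, vc, masked_ids = character(0)) {
  stopifnot(inherits(vc, "variance_components"))
  if (inherits(X, "fixed_design")) {
    ids <- X$ids
    X <- X$X
  } else {
    ids <- names(y)
  }
  if (is.null(ids)) gfb_stop("y must carry ids", "alignment_error")
  if (!is.null(names(y))) y <- y[ids]
  y <- as.numeric(y)
  Gs <- align_grms(grms, ids)
  c_g <- length(Gs)
  if (c_g != length(vc$components)) {
    gfb_stop("number of GRMs does not match the variance components", "structure_error")
  }
  masked_ids <- as.character(masked_ids)
  if (!all(masked_ids %in% ids)) gfb_stop("masked ids not all present", "alignment_error")
  obs <- which(!(ids %in% masked_ids))
  if (!length(obs)) gfb_stop("all individuals are masked; nothing to fit", "structure_error")

  n <- length(ids)
  sig <- vc$components
  V <- diag(vc$residual, length(obs))
  for (i in seq_len(c_g)) V <- V + sig[[i]] * Gs[[i]][obs, obs, drop = FALSE]
  ch <- chol(V)
  Vinv <- chol2inv(ch)
  Xo <- X[obs, , drop = FALSE]
  T_mat <- Vinv %*% Xo
  B <- chol2inv(chol(crossprod(Xo, T_mat)))
  beta <- as.numeric(B %*% crossprod(T_mat, y[obs]))
  names(beta) <- colnames(X)
  r <- y[obs] - as.numeric(Xo %*% beta)
  alpha <- as.numeric(Vinv %*% r)

  gbv <- matrix(0, nrow = n, ncol = c_g, dimnames = list(ids, names(Gs)))
  for (i in seq_len(c_g)) {
    gbv[, i] <- sig[[i]] * as.numeric(Gs[[i]][, obs, drop = FALSE] %*% alpha)
  }
  gbv_total <- rowSums(gbv)
  fixed_fitted <- stats::setNames(as.numeric(X %*% beta), ids)
  fitted <- fixed_fitted[obs] + gbv_total[obs]
  structure(list(
    beta = beta,
    gbv = gbv,
    gbv_total = stats::setNames(gbv_total, ids),
    fixed_fitted = fixed_fitted,
    fitted = fitted,
    residuals = stats::setNames(y[obs] - fitted, ids[obs]),
    vc = vc,
    ids = ids,
    masked_ids = masked_ids
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("model_fit:", length(x$ids), "individuals (", length(x$masked_ids),
      "masked );", ncol(x$gbv), "genomic component(s):",
      paste(colnames(x$gbv), collapse = ", "), "\n")
  invisible(x)
}

#' Heritability from variance components
#'
#' GBLUP: `h2 = sigma_a^2 / (sigma_a^2 + sigma_e^2)`. GFBLUP:
#' `h2 = sigma_total^2 / (sigma_total^2 + sigma_e^2)` with `sigma_total^2`
#' the sum of the per-feature and rest genetic variances.
#'
#' @param vc a `variance_components` object
#' @param model `"gblup"` (one genetic component) or `"gfblup"` (several)
#' @return heritability in \[0, 1\]
#' @export
heritability <- function(vc, model = c("gblup", "gfblup")) {
  model <- match.arg(model)
  stopifnot(inherits(vc, "variance_components"))
  if (model == "gblup" && length(vc$components) != 1L) {
    gfb_stop("gblup heritability expects exactly one genetic component", "structure_error")
  }
  if (model == "gfblup" && length(vc$components) < 2L) {
    gfb_stop("gfblup heritability expects several genetic components", "structure_error")
  }
  s_tot <- sum(vc$components)
  if (s_tot + vc$residual <= 0) {
    gfb_stop("heritability undefined: all variances are zero", "domain_error")
  }
  s_tot / (s_tot + vc$residual)
}
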