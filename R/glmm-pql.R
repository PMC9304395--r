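#' Fit a hierarchical gamma mixed model by penalized quasi-likelihood
#'
#' Stiffness observations are strictly positive, right-skewed and clustered
#' (pixels within maps within patients), so they are modelled with a gamma
#' GLMM with log link, fitted by penalized quasi-likelihood (PQL). The PQL
#' scheme alternates (a) the working-response linearization of the gamma/log
#' GLM, `zeta = eta + (y - mu)/mu`, with (b) a linear mixed-model solve for
#' the fixed effects and random-effect predictions, iterating until the
#' relative change in the fixed effects falls below `tol`. For the gamma/log
#' pair the IRLS weights are identically one, so the working response is
#' homoscedastic and its residual variance estimates the quasi-dispersion.
#' The inner linear mixed-model solve uses [nlme::lme()]; the reported
#' denominator degrees of freedom follow its containment rule. Dispersion is
#' also reported as the moment estimator from Pearson residuals.
#'
#' When every random grouping factor has fewer than two levels the random
#' structure is unidentifiable and the model collapses to an ordinary gamma
#' GLM ([stats::glm()]), which is also the exact limit of PQL at zero
#' random-effect variance.
#'
#' @param data A tibble of observations (one row per measurement).
#' @param fixed Two-sided model formula, e.g. `E_kPa ~ tissue_type`. The
#'   response must be strictly positive.
#' @param random One-sided `nlme`-style grouping formula, e.g.
#'   `~ 1 | patient_id/map_id`. Grouping factors with fewer than two levels
#'   are dropped (with a message) before fitting.
#' @param tol Relative fixed-effect change declaring convergence.
#' @param max_iter Maximum PQL iterations.
#' @return An object of class `gamma_pql` with elements `beta`, `se`, `df`
#'   (containment denominator df per coefficient), `t_value`, `p_value`,
#'   `vcov`, `random_sd` (named vector of random-intercept SDs on the log
#'   scale, plus `residual`), `dispersion` (Pearson), `converged`,
#'   `iterations`, `n_obs`, `term_labels`, `assign`, `collapsed` (TRUE when
#'   fitted as a plain GLM) and the final inner fit as `inner`.
#' @seealso [wald_f_test()], [tidy.gamma_pql()], [glance.gamma_pql()]
#' @export
fit_gamma_glmm <- function(data, fixed, random = ~ 1 | patient_id / map_id,
                           tol = 1e-6, max_iter = 100) {
  data <- as.data.frame(data)
  mf <- stats::model.frame(fixed, data)
  y <- stats::model.response(mf)
  if (any(y <= 0)) stop("the response must be strictly positive", call. = FALSE)

  g_vars <- all.vars(random)
  for (g in g_vars) {
    if (!g %in% names(data)) stop("grouping variable `", g, "` not in data",
                                  call. = FALSE)
    data[[g]] <- factor(data[[g]])
  }
  # drop unidentifiable grouping levels (fewer than 2 distinct groups)
  keep <- g_vars[vapply(g_vars, function(g) nlevels(data[[g]]) >= 2, logical(1))]
  if (length(keep) < length(g_vars)) {
    message("dropping random grouping(s) with a single level: ",
            paste(setdiff(g_vars, keep), collapse = ", "))
  }
  # drop nesting levels that add no grouping resolution (e.g. one map per
  # patient x tissue cell): their variance is confounded with the parent level
  if (length(keep) > 1) {
    cum <- factor(data[[keep[1]]])
    n_prev <- nlevels(cum)
    keep2 <- keep[1]
    for (g in keep[-1]) {
      cum <- interaction(cum, data[[g]], drop = TRUE)
      if (nlevels(cum) > n_prev) {
        keep2 <- c(keep2, g)
        n_prev <- nlevels(cum)
      } else {
        message("dropping redundant nesting level: ", g)
      }
    }
    keep <- keep2
  }
  term_labels0 <- attr(stats::terms(fixed), "term.labels")
  rhs <- if (length(term_labels0) == 0) {
    ~1
  } else {
    stats::reformulate(term_labels0,
                       intercept = attr(stats::terms(fixed), "intercept"))
  }
  X <- stats::model.matrix(rhs, data)
  term_labels <- attr(stats::terms(fixed), "term.labels")
  asn <- attr(X, "assign")

  if (length(keep) == 0) {
    fit0 <- stats::glm(fixed, family = Gamma(link = "log"), data = data)
    sm <- summary(fit0)
    phi <- sum(((y - fitted(fit0)) / fitted(fit0))^2) / fit0$df.residual
    out <- list(
      beta = coef(fit0), se = sm$coefficients[, 2],
      df = rep(fit0$df.residual, length(coef(fit0))),
      t_value = sm$coefficients[, 3],
      p_value = 2 * pt(abs(sm$coefficients[, 3]), fit0$df.residual,
                       lower.tail = FALSE),
      vcov = vcov(fit0), random_sd = c(residual = sqrt(sm$dispersion)),
      dispersion = phi, converged = fit0$converged, iterations = fit0$iter,
      n_obs = length(y), n_groups = integer(0),
      fixed = fixed, random = random, term_labels = term_labels,
      assign = asn, collapsed = TRUE, inner = fit0
    )
    return(structure(out, class = "gamma_pql"))
  }
  random_use <- stats::as.formula(
    paste("~ 1 |", paste(keep, collapse = "/")))

  init <- stats::glm(fixed, family = Gamma(link = "log"), data = data)
  eta <- as.numeric(predict(init, type = "link"))
  beta_old <- coef(init)
  fixed_w <- stats::update(fixed, .pql_z ~ .)
  ctrl <- nlme::lmeControl(opt = "optim", returnObject = TRUE,
                           maxIter = 100, msMaxIter = 100, niterEM = 25)
  converged <- FALSE
  m <- NULL
  iter <- 0
  solve_lmm <- function(dat) {
    for (optimizer in c("optim", "nlminb")) {
      ctrl$opt <- optimizer
      m_try <- tryCatch(
        suppressWarnings(
          nlme::lme(fixed_w, random = random_use, data = dat,
                    method = "REML", control = ctrl)
        ),
        error = function(e) NULL
      )
      if (!is.null(m_try)) return(m_try)
    }
    NULL
  }
  for (iter in seq_len(max_iter)) {
    mu <- exp(eta)
    data$.pql_z <- eta + (y - mu) / mu
    m_new <- solve_lmm(data)
    if (is.null(m_new)) {
      if (is.null(m)) {
        stop("inner linear mixed-model solve failed (singular random ",
             "structure)", call. = FALSE)
      }
      break  # keep the previous iterate
    }
    m <- m_new
    eta <- as.numeric(fitted(m))  # includes random-effect predictions
    beta <- nlme::fixef(m)
    delta <- max(abs(beta - beta_old) / pmax(abs(beta_old), 1e-8))
    beta_old <- beta
    if (delta < tol) { converged <- TRUE; break }
  }
  mu <- exp(eta)
  phi <- sum(((y - mu) / mu)^2) / (length(y) - length(beta_old))
  sm <- summary(m)$tTable
  vc <- extract_varcorr(m)
  out <- list(
    beta = nlme::fixef(m), se = sm[, "Std.Error"], df = sm[, "DF"],
    t_value = sm[, "t-value"], p_value = sm[, "p-value"],
    vcov = vcov(m), random_sd = vc, dispersion = phi,
    converged = converged, iterations = iter,
    n_obs = length(y),
    n_groups = vapply(keep, function(g) nlevels(data[[g]]), integer(1)),
    fixed = fixed, random = random_use, term_labels = term_labels,
    assign = asn, collapsed = FALSE, inner = m
  )
  structure(out, class = "gamma_pql")
}

# random-intercept SDs (plus residual) from an lme fit, named by grouping
extract_varcorr <- function(m) {
  vc <- nlme::VarCorr(m)
  rn <- rownames(vc)
  sds <- suppressWarnings(as.numeric(vc[, "StdDev"]))
  if (!any(grepl("=", rn))) {
    # single grouping level: rows are (Intercept), Residual without headers
    lab <- tryCatch(deparse(nlme::getGroupsFormula(m)[[2]]),
                    error = function(e) "group")
    out <- setNames(sds[match(c("(Intercept)", "Residual"), rn)],
                    c(lab, "residual"))
    return(out[!is.na(out)])
  }
  group <- NA_character_
  out <- numeric(0)
  for (i in seq_along(rn)) {
    if (grepl("=", rn[i])) {
      group <- sub(" =.*", "", rn[i])
    } else if (rn[i] == "(Intercept)" && !is.na(sds[i]) && !is.na(group)) {
      out[group] <- sds[i]
    } else if (rn[i] == "Residual") {
      out["residual"] <- sds[i]
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wald F test for a fixed-effect term
#'
#' Tests all coefficients of one model term jointly:
#' \deqn{F = (C\beta)^\top (C V C^\top)^{-1} (C\beta) / q,}
#' with `C` selecting the term's `q` coefficients and `V` the fixed-effect
#' covariance. The Wald form is used instead of likelihood ratios because
#' the quasi-likelihood fit has no true likelihood and the data are
#' overdispersed. The denominator degrees of freedom follow the containment
#' rule (the term is tested at the grouping level it varies within), taken
#' as the smallest per-coefficient containment df of the term.
#'
#' @param fit A [fit_gamma_glmm()] fit.
#' @param term A term name from `fit$term_labels`.
#' @return A one-row tibble: `term`, `F_value`, `ndf`, `ddf`, `p_value`.
#' @export
wald_f_test <- function(fit, term) {
  stopifnot(inherits(fit, "gamma_pql"))
  w <- which(fit$term_labels == term)
  if (length(w) != 1) {
    stop("`term` must be one of: ", paste(fit$term_labels, collapse = ", "),
         call. = FALSE)
  }
  idx <- which(fit$assign == w)
  if (length(idx) == 0) stop("term has no estimated coefficients", call. = FALSE)
  b <- fit$beta[idx]
  V <- as.matrix(fit$vcov)[idx, idx, drop = FALSE]
  q <- length(idx)
  Vi <- tryCatch(solve(V), error = function(e) {
    stop("rank-deficient contrast for term `", term, "`", call. = FALSE)
  })
  Fv <- as.numeric(t(b) %*% Vi %*% b) / q
  ddf <- min(fit$df[idx])
  tibble::tibble(term = term, F_value = Fv, ndf = q, ddf = ddf,
                 p_value = pf(Fv, q, ddf, lower.tail = FALSE))
}

#' @export
print.gamma_pql <- function(x, ...) {
  cat("<gamma_pql> gamma GLMM (log link) fitted by PQL\n")
  cat("  fixed:  ", deparse(x$fixed), "\n")
  if (!x$collapsed) {
    cat("  random: ", deparse(x$random), "\n")
  } else {
    cat("  random:  none (collapsed to gamma GLM)\n")
  }
  cat(sprintf("  %d obs, dispersion %.3f, %s after %d iteration(s)\n",
              x$n_obs, x$dispersion,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(tidy.gamma_pql(x), n = Inf)
  invisible(x)
}

#' Tidy a PQL gamma mixed-model fit
#'
#' @param x A `gamma_pql` object.
#' @param ... Unused.
#' @return A tibble with one row per fixed-effect coefficient: `term`,
#'   `estimate` (log scale), `std.error`, `df`, `statistic`, `p.value`.
#' @method tidy gamma_pql
#' @export
tidy.gamma_pql <- function(x, ...) {
  tibble::tibble(
    term = names(x$beta), estimate = unname(x$beta),
    std.error = unname(x$se), df = unname(x$df),
    statistic = unname(x$t_value), p.value = unname(x$p_value)
  )
}

#' One-row summary of a PQL gamma mixed-model fit
#'
#' @param x A `gamma_pql` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_obs`, `dispersion`, `iterations`,
#'   `converged`, `collapsed`, plus one `sd_*` column per random grouping.
#' @method glance gamma_pql
#' @export
glance.gamma_pql <- function(x, ...) {
  g <- tibble::tibble(n_obs = x$n_obs, dispersion = x$dispersion,
                      iterations = x$iterations, converged = x$converged,
                      collapsed = x$collapsed)
  if (length(x$random_sd)) {
    sds <- tibble::as_tibble(as.list(setNames(
      x$random_sd, paste0("sd_", names(x$random_sd)))))
    g <- dplyr::bind_cols(g, sds)
  }
  g
}
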