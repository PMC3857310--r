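# Stepwise linear discriminant analysis with Mahalanobis variable selection:
# validates profile cluster assignments and classifies held-out (e.g.
# ancestral) hydropathy profiles.

#' Configuration for stepwise discriminant analysis
#'
#' @param f_enter F-to-enter threshold (default 3.84, the chi-square 1 df
#'   5 percent point, the conventional stepwise default).
#' @param f_remove F-to-remove threshold (default 2.71, the 10 percent
#'   point); must be smaller than `f_enter`.
#' @param priors `"by-size"` (group priors proportional to group size, the
#'   default) or `"equal"`.
#' @param max_steps Maximum number of entry steps (default unlimited).
#' @return A list of class `discriminant_config`.
#' @export
discriminant_config <- function(f_enter = 3.84, f_remove = 2.71,
                                priors = c("by-size", "equal"),
                                max_steps = Inf) {
  priors <- match.arg(priors)
  if (!(f_enter > 0 && f_remove > 0)) stop("thresholds must be positive", call. = FALSE)
  if (f_remove >= f_enter) stop("f_remove must be smaller than f_enter", call. = FALSE)
  structure(list(f_enter = f_enter, f_remove = f_remove, priors = priors,
                 max_steps = max_steps),
            class = "discriminant_config")
}

# per-group counts/means and pooled within-group covariance over all columns
group_stats <- function(X, labels) {
  labels <- factor(labels)
  groups <- levels(labels)
  g <- length(groups)
  n <- nrow(X)
  counts <- as.integer(table(labels))
  res <- vapply(groups, function(gr) colMeans(X[labels == gr, , drop = FALSE]),
                numeric(ncol(X)))
  means <- if (is.matrix(res)) t(res) else matrix(res, ncol = 1L)
  dimnames(means) <- list(groups, colnames(X))
  Sw <- matrix(0, ncol(X), ncol(X), dimnames = list(colnames(X), colnames(X)))
  for (gr in groups) {
    Xg <- X[labels == gr, , drop = FALSE]
    Xg <- sweep(Xg, 2L, colMeans(Xg))
    Sw <- Sw + crossprod(Xg)
  }
  pooled <- Sw / (n - g)
  list(labels = labels, groups = groups, g = g, n = n, counts = counts,
       means = means, pooled = pooled)
}

# pairwise Mahalanobis D^2 between group means on a variable subset;
# returns NULL if the pooled covariance on the subset is singular
pair_d2 <- function(gs, vars) {
  S <- gs$pooled[vars, vars, drop = FALSE]
  Sinv <- tryCatch(chol2inv(chol(S)), error = function(e) NULL)
  if (is.null(Sinv)) return(NULL)
  pairs <- utils::combn(gs$g, 2L)
  d2 <- apply(pairs, 2L, function(ij) {
    d <- gs$means[ij[1L], vars] - gs$means[ij[2L], vars]
    drop(t(d) %*% Sinv %*% d)
  })
  list(pairs = pairs, d2 = d2)
}

# Hotelling T^2 for a group pair from its Mahalanobis D^2
t2_of <- function(gs, ij, d2) {
  ni <- gs$counts[ij[1L]]; nj <- gs$counts[ij[2L]]
  (ni * nj / (ni + nj)) * d2
}

# partial F for going from p variables (T2 = t2_old, on the same pair) to
# p+1 variables (T2 = t2_new); m = n - g.  Classical increment-in-T^2 form:
#   F = (m - p) * (T2_new - T2_old) / (m + T2_old)
partial_f <- function(m, p, t2_old, t2_new) {
  (m - p) * (t2_new - t2_old) / (m + t2_old)
}

# D^2 of a specific pair on a variable subset (0 for the empty set)
pair_d2_single <- function(gs, vars, ij) {
  if (length(vars) == 0L) return(0)
  S <- gs$pooled[vars, vars, drop = FALSE]
  Sinv <- tryCatch(chol2inv(chol(S)), error = function(e) NULL)
  if (is.null(Sinv)) return(NA_real_)
  d <- gs$means[ij[1L], vars] - gs$means[ij[2L], vars]
  drop(t(d) %*% Sinv %*% d)
}

#' Fit a stepwise linear discriminant model (Mahalanobis selection)
#'
#' Variables are entered greedily so as to maximize the smallest pairwise
#' Mahalanobis distance \eqn{D^2} between group means (i.e. the separation of
#' the two closest groups), each entry being admitted only if its partial
#' F-to-enter exceeds `cfg$f_enter`; after every entry, any previously
#' entered variable whose F-to-remove falls below `cfg$f_remove` is dropped.
#' The partial F is the classical increment form for the closest pair's
#' Hotelling \eqn{T^2} (see `partial_f` in the source). Selection stops when
#' no candidate qualifies.
#'
#' Classification uses Fisher's linear classification functions with the
#' pooled within-group covariance:
#' \eqn{s_k(x) = \mu_k' \Sigma^{-1} x - \tfrac12 \mu_k' \Sigma^{-1} \mu_k +
#' \ln \pi_k}. Canonical discriminant coefficients (scaled so canonical
#' scores have unit pooled within-group variance) are also returned.
#'
#' @param X Numeric profile matrix (rows = cases) with column names.
#' @param labels Group labels, one per row; at least 2 groups with at least
#'   2 members each.
#' @param cfg A [discriminant_config()].
#' @return An object of class `discriminant_model`: list with `variables`
#'   (in entry order), `groups`, `counts`, `priors`, `means` (groups x
#'   selected variables), `pooled_cov`, `fisher_coef` (variables x groups),
#'   `fisher_const` (per-group intercepts incl. log prior), `canonical`
#'   (variables x functions), and a `steps` log data frame.
#' @export
fit_stepwise <- function(X, labels, cfg = discriminant_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- as.character(seq_len(ncol(X)))
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(labels) < 2L)) stop("every group needs at least 2 members", call. = FALSE)
  if (nrow(X) != length(labels)) stop("labels length must match rows of X", call. = FALSE)

  gs <- group_stats(X, labels)
  m <- gs$n - gs$g
  # drop zero pooled-variance columns up front
  usable <- colnames(X)[diag(gs$pooled) > 0]
  if (length(usable) == 0L) stop("all variables have zero pooled variance", call. = FALSE)

  selected <- character(0L)
  steps <- list()
  repeat {
    if (length(steps) >= cfg$max_steps) break
    candidates <- setdiff(usable, selected)
    if (length(candidates) == 0L) break
    p <- length(selected)
    if (m - p <= 1L) break  # out of error degrees of freedom
    best <- NULL
    for (v in candidates) {
      res <- pair_d2(gs, c(selected, v))
      if (is.null(res)) next  # singular with this variable: skip
      k <- which.min(res$d2)
      cand <- list(var = v, min_d2 = res$d2[k], pair = res$pairs[, k])
      if (is.null(best) || cand$min_d2 > best$min_d2) best <- cand
    }
    if (is.null(best)) {
      warning("remaining candidate variables all give a singular pooled covariance")
      break
    }
    d2_old <- pair_d2_single(gs, selected, best$pair)
    t2_old <- if (p == 0L) 0 else t2_of(gs, best$pair, d2_old)
    t2_new <- t2_of(gs, best$pair, best$min_d2)
    f_enter <- partial_f(m, p, t2_old, t2_new)
    if (!is.finite(f_enter) || f_enter < cfg$f_enter) break
    selected <- c(selected, best$var)
    steps[[length(steps) + 1L]] <- data.frame(
      action = "enter", variable = best$var, F = f_enter,
      min_d2 = best$min_d2, stringsAsFactors = FALSE)

    # removal sweep (never the variable just entered)
    repeat {
      removable <- setdiff(selected, best$var)
      if (length(removable) == 0L) break
      p_now <- length(selected)
      res_full <- pair_d2(gs, selected)
      if (is.null(res_full)) break
      kf <- which.min(res_full$d2)
      pair_f <- res_full$pairs[, kf]
      t2_full <- t2_of(gs, pair_f, res_full$d2[kf])
      f_rm <- vapply(removable, function(w) {
        red <- setdiff(selected, w)
        d2_red <- pair_d2_single(gs, red, pair_f)
        if (is.na(d2_red)) return(Inf)
        t2_red <- t2_of(gs, pair_f, d2_red)
        partial_f(m, p_now - 1L, t2_red, t2_full)
      }, numeric(1L))
      worst <- which.min(f_rm)
      if (f_rm[worst] >= cfg$f_remove) break
      w <- removable[worst]
      selected <- setdiff(selected, w)
      steps[[length(steps) + 1L]] <- data.frame(
        action = "remove", variable = w, F = f_rm[worst],
        min_d2 = min(pair_d2(gs, selected)$d2), stringsAsFactors = FALSE)
    }
  }

  if (length(selected) == 0L) {
    stop("no variable passes the entry criterion: groups are not separable ",
         "at f_enter = ", cfg$f_enter, " (empty model)", call. = FALSE)
  }

  build_discriminant_model(X[, selected, drop = FALSE], labels, cfg,
                           variables = selected,
                           steps = do.call(rbind, steps))
}

# assemble the classification machinery for a fixed variable set
build_discriminant_model <- function(Xs, labels, cfg, variables,
                                     steps = NULL) {
  gs <- group_stats(Xs, labels)
  priors <- if (cfg$priors == "by-size") gs$counts / gs$n else rep(1 / gs$g, gs$g)
  names(priors) <- gs$groups
  Sinv <- chol2inv(chol(gs$pooled))
  coef <- Sinv %*% t(gs$means)                       # p x g
  const <- -0.5 * colSums(t(gs$means) * coef) + log(priors)
  # canonical functions: eigenvectors of W^-1 B, scaled to unit pooled
  # within-group variance of the scores
  mu_bar <- colSums(gs$means * gs$counts) / gs$n
  B <- matrix(0, ncol(Xs), ncol(Xs))
  for (k in seq_len(gs$g)) {
    d <- gs$means[k, ] - mu_bar
    B <- B + gs$counts[k] * tcrossprod(d)
  }
  B <- B / (gs$g - 1)
  eig <- eigen(Sinv %*% B)
  n_fun <- min(gs$g - 1L, ncol(Xs))
  canonical <- Re(eig$vectors[, seq_len(n_fun), drop = FALSE])
  for (j in seq_len(n_fun)) {
    a <- canonical[, j]
    s <- sqrt(drop(t(a) %*% gs$pooled %*% a))
    if (s > 0) canonical[, j] <- a / s
  }
  dimnames(canonical) <- list(variables, paste0("LD", seq_len(n_fun)))
  dimnames(coef) <- list(variables, gs$groups)
  structure(list(variables = variables, groups = gs$groups,
                 counts = stats::setNames(gs$counts, gs$groups),
                 priors = priors,
                 means = gs$means, pooled_cov = gs$pooled,
                 fisher_coef = coef, fisher_const = const,
                 canonical = canonical, config = cfg, steps = steps),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat("Stepwise discriminant model:", length(x$variables), "variable(s) [",
      paste(x$variables, collapse = ", "), "],", length(x$groups), "groups\n")
  invisible(x)
}

#' Classify profiles with a fitted discriminant model
#'
#' Applies Fisher's linear classification functions; the posterior for group
#' k is the softmax of the linear scores. Ties in the argmax are broken by
#' group order.
#'
#' @param model A [fit_stepwise()] model.
#' @param X Profile matrix containing (at least) the model's selected
#'   variables as named columns.
#' @return List with `class` (factor of assignments), `posterior` (cases x
#'   groups matrix, rows summing to 1) and `scores` (the linear scores).
#' @export
classify <- function(model, X) {
  stopifnot(inherits(model, "discriminant_model"))
  X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X) == length(model$variables)) {
    colnames(X) <- model$variables
  }
  missing_vars <- setdiff(model$variables, colnames(X))
  if (length(missing_vars) > 0L) {
    stop("profiles lack model variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  Xs <- X[, model$variables, drop = FALSE]
  scores <- Xs %*% model$fisher_coef
  scores <- sweep(scores, 2L, model$fisher_const, "+")
  shifted <- scores - apply(scores, 1L, max)
  post <- exp(shifted) / rowSums(exp(shifted))
  cls <- factor(model$groups[max.col(scores, ties.method = "first")],
                levels = model$groups)
  dimnames(post) <- list(rownames(X), model$groups)
  list(class = cls, posterior = post, scores = scores)
}

#' Leave-one-out cross-validation of the discriminant model
#'
#' The variable set is fixed from the full stepwise fit (re-running selection
#' within each fold is available via `refit_selection`); for each case the
#' group means, pooled covariance and priors are re-estimated with the case
#' excluded and the case is then classified. Reports both the resubstitution
#' ("original grouped cases") and the cross-validated fraction correctly
#' classified.
#'
#' @param X Profile matrix with column names.
#' @param labels Group labels.
#' @param cfg A [discriminant_config()].
#' @param refit_selection Re-run stepwise selection inside every fold
#'   (default `FALSE`).
#' @return Object of class `cv_report`: list with `original_accuracy`,
#'   `loo_accuracy`, `model`, and `cases` (a data frame of per-case truth,
#'   resubstitution and LOO assignments and LOO posterior of the assigned
#'   group; `loo_class` is `NA` for skipped cases).
#' @export
cross_validate_loo <- function(X, labels, cfg = discriminant_config(),
                               refit_selection = FALSE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- as.character(seq_len(ncol(X)))
  labels <- factor(labels)
  model <- tryCatch(fit_stepwise(X, labels, cfg), error = function(e) {
    if (grepl("empty model", conditionMessage(e))) NULL else stop(e)
  })
  if (is.null(model)) {
    # no variable separates the groups: classification falls back to the
    # prior alone, i.e. every case goes to the largest group
    warning("no variable passed the entry criterion; ",
            "classifying by group priors alone")
    return(prior_only_cv(labels))
  }
  resub <- classify(model, X)
  n <- nrow(X)
  loo_class <- factor(rep(NA_character_, n), levels = model$groups)
  loo_post <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lab_i <- labels[-i]
    if (any(table(lab_i) < 2L)) {
      warning("case ", i, " skipped in LOO: a group would drop below 2 members")
      next
    }
    fold_model <- if (refit_selection) {
      tryCatch(fit_stepwise(X[-i, , drop = FALSE], lab_i, cfg),
               error = function(e) NULL)
    } else {
      build_discriminant_model(X[-i, model$variables, drop = FALSE], lab_i,
                               cfg, variables = model$variables)
    }
    if (is.null(fold_model)) next
    pred <- classify(fold_model, X[i, , drop = FALSE])
    loo_class[i] <- as.character(pred$class)
    loo_post[i] <- max(pred$posterior)
  }
  ok <- !is.na(loo_class)
  cases <- data.frame(truth = labels,
                      resub_class = resub$class,
                      loo_class = loo_class,
                      loo_posterior = loo_post)
  structure(list(
    original_accuracy = mean(resub$class == labels),
    loo_accuracy = mean(loo_class[ok] == labels[ok]),
    model = model,
    cases = cases), class = "cv_report")
}

# degenerate cross-validation report when the stepwise model is empty:
# every case is assigned to the group with the largest prior (= largest
# group under by-size priors; ties broken by group order)
prior_only_cv <- function(labels) {
  groups <- levels(labels)
  biggest <- groups[which.max(table(labels))]
  n <- length(labels)
  loo_class <- vapply(seq_len(n), function(i) {
    tab <- table(labels[-i])
    names(tab)[which.max(tab)]
  }, character(1L))
  cases <- data.frame(truth = labels,
                      resub_class = factor(rep(biggest, n), levels = groups),
                      loo_class = factor(loo_class, levels = groups),
                      loo_posterior = NA_real_)
  structure(list(original_accuracy = mean(labels == biggest),
                 loo_accuracy = mean(loo_class == as.character(labels)),
                 model = NULL, cases = cases),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Original grouped cases correct: %.1f%%\n",
              100 * x$original_accuracy))
  cat(sprintf("Cross-validated (LOO) correct:  %.1f%%\n",
              100 * x$loo_accuracy))
  invisible(x)
}
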