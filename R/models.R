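# Five occurrence-model algorithms behind one fit/predict/response-curve
# contract. GLM, GAM and the MaxEnt-equivalent work on z-scored covariates;
# the tree methods use raw values. All stochastic fitters are seeded.

SUPPORTED_ALGORITHMS <- c("GLM", "GAM", "MAXENT", "BRT", "RF")

#' Specify a model algorithm and its hyperparameters
#'
#' Hyperparameter defaults: GAM uses penalised thin-plate smooths with basis
#' dimension `k = 5` (about 4 effective df per covariate); the
#' MaxEnt-equivalent uses `n_hinge = 5` hinge knots per covariate in each
#' direction and 5-fold internal cross-validation for the lasso penalty; BRT
#' uses depth-3 trees, learning rate 0.01, bag fraction 0.5, and picks the
#' tree count by a 20% internal holdout (cap `n_trees = 500`); RF grows 500
#' trees with `mtry = 2` and vote-fraction probabilities.
#'
#' @param id One of `"GLM"`, `"GAM"`, `"MAXENT"`, `"BRT"`, `"RF"`.
#' @param ... Hyperparameter overrides (see Details above for names).
#' @param seed Integer seed for stochastic fitters.
#' @return An `algorithm_spec` list.
#' @export
algorithm_spec <- function(id, ..., seed = 1L) {
  id <- toupper(id)
  if (!id %in% SUPPORTED_ALGORITHMS) {
    rlang::abort(sprintf("unsupported algorithm '%s'; use one of %s", id,
                         paste(SUPPORTED_ALGORITHMS, collapse = ", ")),
                 class = "climenvelope_config_error")
  }
  defaults <- switch(id,
    GLM = list(),
    GAM = list(k = 5),
    MAXENT = list(n_hinge = 5, nfolds = 5),
    BRT = list(n_trees = 500, depth = 3, learning_rate = 0.01,
               bag_fraction = 0.5, holdout_fraction = 0.2, min_node = 10),
    RF = list(n_trees = 500, mtry = 2, min_node = 5))
  hp <- utils::modifyList(defaults, list(...))
  structure(list(id = id, hyperparameters = hp, seed = as.integer(seed)),
            class = "algorithm_spec")
}

# z-scoring parameters from training data; constant columns get sd 1 so the
# standardised column is identically 0 rather than NaN
standardiser <- function(table, covariates = bioclim_vars()) {
  mu <- vapply(covariates, function(b) mean(table[[b]]), numeric(1))
  sd <- vapply(covariates, function(b) stats::sd(table[[b]]), numeric(1))
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}

apply_standardiser <- function(data, std, vars = names(std$mu)) {
  out <- lapply(vars, function(b) (data[[b]] - std$mu[[b]]) / std$sd[[b]])
  names(out) <- vars
  as.data.frame(out)
}

#' Fit a species distribution model
#'
#' Fits one of the five supported algorithms to a feature table (see
#' [assemble_training_set()]). GLM is a binomial regression with linear and
#' quadratic terms per covariate; GAM a binomial additive model with
#' penalised smooths; MAXENT the maximum-entropy presence/background model
#' in its L1-regularised logistic form with linear, quadratic and hinge
#' features, background rows reweighted so total background weight equals
#' total presence weight; BRT logistic gradient boosting over depth-limited
#' regression trees with Newton leaf updates; RF a random forest with
#' vote-fraction probabilities.
#'
#' @param table Feature table with `response` and the five [bioclim_vars()].
#' @param spec An [algorithm_spec()].
#' @param covariates Covariate columns to use (default all five); used by
#'   the leave-one-covariate-out importance analysis.
#' @return An `sdm_model` object supporting [predict()][predict.sdm_model],
#'   [response_curve()], [generics::tidy()] and [generics::glance()].
#' @export
fit_sdm <- function(table, spec, covariates = bioclim_vars()) {
  stopifnot(inherits(spec, "algorithm_spec"))
  assert_has_cols(table, c("response", covariates), "feature table")
  for (b in covariates) assert_finite(table[[b]], b)
  if (length(unique(table$response)) < 2) {
    rlang::abort("response has a single class; cannot fit",
                 class = "climenvelope_degenerate_fit_error")
  }
  y <- as.integer(table$response)
  std <- standardiser(table, covariates)
  ranges <- lapply(covariates, function(b) range(table[[b]]))
  names(ranges) <- covariates
  means <- vapply(covariates, function(b) mean(table[[b]]), numeric(1))

  fitted <- switch(spec$id,
    GLM = fit_glm_engine(table, y, std, covariates),
    GAM = fit_gam_engine(table, y, std, covariates, spec$hyperparameters),
    MAXENT = fit_maxent_engine(table, y, std, covariates,
                               spec$hyperparameters, spec$seed),
    BRT = fit_brt_engine(table, y, covariates, spec$hyperparameters, spec$seed),
    RF = fit_rf_engine(table, y, covariates, spec$hyperparameters, spec$seed))

  structure(list(
    algorithm = spec,
    fit = fitted,
    covariates = covariates,
    standardiser = std,
    ranges = ranges,
    means = means,
    n_presence = sum(y == 1),
    n_background = sum(y == 0)
  ), class = c(paste0("sdm_", tolower(spec$id)), "sdm_model"))
}

# ---- GLM: binomial regression, linear + quadratic per covariate -----------

glm_design <- function(data, std, covariates) {
  z <- apply_standardiser(data, std, covariates)
  df <- z
  for (b in covariates) df[[paste0(b, "_sq")]] <- z[[b]]^2
  df
}

fit_glm_engine <- function(table, y, std, covariates) {
  df <- glm_design(table, std, covariates)
  df$.y <- y
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial()))
  list(model = fit)
}

predict_glm_engine <- function(object, newdata) {
  df <- glm_design(newdata, object$standardiser, object$covariates)
  as.numeric(suppressWarnings(
    predict(object$fit$model, newdata = df, type = "response")))
}

# ---- GAM: binomial additive model with penalised smooths ------------------

fit_gam_engine <- function(table, y, std, covariates, hp) {
  z <- apply_standardiser(table, std, covariates)
  z$.y <- y
  # constant (zero-variance) covariates enter linearly: s() needs spread
  smooth_ok <- vapply(covariates, function(b) length(unique(z[[b]])) > hp$k,
                      logical(1))
  terms <- ifelse(smooth_ok,
                  sprintf("s(%s, k = %d)", covariates, hp$k),
                  covariates)
  form <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  fit <- mgcv::gam(form, data = z, family = stats::binomial(),
                   method = "REML")
  list(model = fit)
}

predict_gam_engine <- function(object, newdata) {
  z <- apply_standardiser(newdata, object$standardiser, object$covariates)
  as.numeric(predict(object$fit$model, newdata = z, type = "response"))
}

# ---- MAXENT: L1-regularised presence/background logistic ------------------

maxent_features <- function(z, knots) {
  cols <- list()
  for (b in names(z)) {
    x <- z[[b]]
    cols[[b]] <- x
    cols[[paste0(b, "_sq")]] <- x^2
    for (j in seq_along(knots[[b]])) {
      k <- knots[[b]][j]
      cols[[paste0(b, "_hu", j)]] <- pmax(0, x - k)
      cols[[paste0(b, "_hd", j)]] <- pmax(0, k - x)
    }
  }
  do.call(cbind, cols)
}

fit_maxent_engine <- function(table, y, std, covariates, hp, seed) {
  z <- apply_standardiser(table, std, covariates)
  probs <- seq(0.05, 0.95, length.out = hp$n_hinge)
  knots <- lapply(z, function(x) unique(quantile(x, probs, names = FALSE)))
  X <- maxent_features(z, knots)
  if (all(apply(X, 2, function(col) length(unique(col)) == 1L))) {
    rlang::abort("all MAXENT features are constant; cannot fit",
                 class = "climenvelope_degenerate_fit_error")
  }
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  w <- ifelse(y == 1, 1, n1 / n0)
  foldid <- withr::with_seed(seed, sample(rep_len(seq_len(hp$nfolds), length(y))))
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", weights = w,
                          alpha = 1, foldid = foldid, standardize = FALSE)
  list(model = cv, knots = knots, lambda = cv$lambda.min)
}

predict_maxent_engine <- function(object, newdata) {
  z <- apply_standardiser(newdata, object$standardiser, object$covariates)
  X <- maxent_features(z, object$fit$knots)
  as.numeric(predict(object$fit$model, newx = X, s = "lambda.min",
                     type = "response"))
}

# ---- BRT: logistic gradient boosting on CART trees ------------------------

fit_brt_engine <- function(table, y, covariates, hp, seed) {
  X <- as.matrix(table[, covariates])
  n <- length(y)
  withr::with_seed(seed, {
    # stratified internal holdout so both classes stay in the training part
    idx1 <- which(y == 1); idx0 <- which(y == 0)
    h1 <- max(min(round(hp$holdout_fraction * length(idx1)), length(idx1) - 1L), 0L)
    h0 <- max(min(round(hp$holdout_fraction * length(idx0)), length(idx0) - 1L), 0L)
    hold <- c(idx1[sample.int(length(idx1), h1)],
              idx0[sample.int(length(idx0), h0)])
    train <- setdiff(seq_len(n), hold)
    yt <- y[train]; Xt <- X[train, , drop = FALSE]
    yh <- y[hold]; Xh <- X[hold, , drop = FALSE]
    p0 <- mean(yt)
    f0 <- stats::qlogis(min(max(p0, 1e-6), 1 - 1e-6))
    Ft <- rep(f0, length(train))
    Fh <- rep(f0, length(hold))
    trees <- vector("list", hp$n_trees)
    dev_hold <- numeric(hp$n_trees)
    tree_seeds <- sample.int(.Machine$integer.max, hp$n_trees)
    for (m in seq_len(hp$n_trees)) {
      pt <- plogis(Ft)
      r <- yt - pt
      bag <- sample.int(length(train), max(2L, round(hp$bag_fraction * length(train))))
      tree <- .cart_grow(Xt, r, as.integer(bag - 1L), ncol(Xt),
                         hp$depth, hp$min_node, tree_seeds[m])
      leaf_t <- .cart_leaf(tree, Xt) + 1L
      # Newton step per leaf from the in-bag members
      hsum <- pt * (1 - pt)
      num <- tapply(r[bag], leaf_t[bag], sum)
      den <- tapply(hsum[bag], leaf_t[bag], sum)
      gamma <- rep(0, length(tree$value))
      lid <- as.integer(names(num))
      g <- as.numeric(num) / pmax(as.numeric(den), 1e-6)
      gamma[lid] <- pmin(pmax(g, -4), 4)
      tree$value <- gamma
      trees[[m]] <- tree
      Ft <- Ft + hp$learning_rate * gamma[leaf_t]
      Fh <- Fh + hp$learning_rate * .cart_predict(tree, Xh)
      ph <- plogis(Fh)
      dev_hold[m] <- -2 * sum(yh * log(pmax(ph, 1e-12)) +
                              (1 - yh) * log(pmax(1 - ph, 1e-12)))
    }
    best <- which.min(dev_hold)
  })
  list(trees = trees[seq_len(best)], f0 = f0,
       learning_rate = hp$learning_rate, best_iter = best,
       holdout_deviance = dev_hold)
}

predict_brt_engine <- function(object, newdata) {
  X <- as.matrix(newdata[, object$covariates])
  f <- rep(object$fit$f0, nrow(X))
  for (tree in object$fit$trees) {
    f <- f + object$fit$learning_rate * .cart_predict(tree, X)
  }
  plogis(f)
}

# ---- RF: bootstrap forest with vote-fraction probabilities ----------------

fit_rf_engine <- function(table, y, covariates, hp, seed) {
  X <- as.matrix(table[, covariates])
  n <- length(y)
  withr::with_seed(seed, {
    tree_seeds <- sample.int(.Machine$integer.max, hp$n_trees)
    trees <- vector("list", hp$n_trees)
    for (b in seq_len(hp$n_trees)) {
      boot <- sample.int(n, n, replace = TRUE)
      trees[[b]] <- .cart_grow(X, as.numeric(y), as.integer(boot - 1L),
                               hp$mtry, 0L, hp$min_node, tree_seeds[b])
    }
  })
  list(trees = trees)
}

predict_rf_engine <- function(object, newdata) {
  X <- as.matrix(newdata[, object$covariates])
  votes <- rep(0, nrow(X))
  for (tree in object$fit$trees) {
    votes <- votes + as.numeric(.cart_predict(tree, X) >= 0.5)
  }
  votes / length(object$fit$trees)
}

# ---- shared surface --------------------------------------------------------

#' Predict probability of occurrence
#'
#' @param object An `sdm_model`.
#' @param newdata Data frame containing the model's covariate columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.sdm_model <- function(object, newdata, ...) {
  assert_has_cols(newdata, object$covariates, "newdata")
  p <- switch(object$algorithm$id,
    GLM = predict_glm_engine(object, newdata),
    GAM = predict_gam_engine(object, newdata),
    MAXENT = predict_maxent_engine(object, newdata),
    BRT = predict_brt_engine(object, newdata),
    RF = predict_rf_engine(object, newdata))
  pmin(pmax(p, 0), 1)
}

#' @exportS3Method base::print
print.sdm_model <- function(x, ...) {
  cat(sprintf("<sdm_model:%s> %d covariates | %d presences, %d background\n",
              x$algorithm$id, length(x$covariates),
              x$n_presence, x$n_background))
  invisible(x)
}

#' Partial response curve of a fitted model
#'
#' Evaluates the model along a grid of values of one covariate while all
#' other covariates are held constant at their training means — the standard
#' partial response plot for climate-envelope models.
#'
#' @param model An `sdm_model`.
#' @param variable One of the model's covariates.
#' @param n_grid Number of grid points spanning the training range.
#' @return A `response_curve` tibble with columns `variable`, `value`,
#'   `probability`.
#' @export
response_curve <- function(model, variable, n_grid = 100) {
  if (!variable %in% model$covariates) {
    rlang::abort(sprintf("unknown variable '%s'", variable),
                 class = "climenvelope_schema_error")
  }
  rng <- model$ranges[[variable]]
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  newdata <- as.data.frame(as.list(model$means))[rep(1, n_grid), , drop = FALSE]
  newdata[[variable]] <- grid
  p <- predict(model, newdata)
  out <- tibble(variable = variable, value = grid, probability = p)
  attr(out, "held_at") <- model$means[setdiff(model$covariates, variable)]
  attr(out, "algorithm") <- model$algorithm$id
  class(out) <- c("response_curve", class(tibble()))
  out
}

#' Half-maximum crossing of a declining response curve
#'
#' Finds the covariate value of the final descent of the partial response
#' through half of its maximum — the last downward crossing, with linear
#' interpolation between grid points. For a monotone-declining envelope this
#' is the unique crossing; for wiggly fits (e.g. lasso hinge features) the
#' last crossing identifies the upper limit above which the response stays
#' low, which is the threshold the envelope is meant to recover.
#'
#' @param curve A [response_curve()].
#' @return The crossing value, or `NA` if the curve never ends below half
#'   its maximum.
#' @export
response_halfmax <- function(curve) {
  p <- curve$probability
  x <- curve$value
  target <- max(p) / 2
  below <- p <= target
  if (!below[length(p)]) return(NA_real_)
  # last index where the curve sits above target before staying below
  i <- max(which(!below))
  if (i == length(p)) return(NA_real_)
  f <- (p[i] - target) / (p[i] - p[i + 1])
  x[i] + f * (x[i + 1] - x[i])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an sdm_model
#'
#' GLM and MAXENT return coefficient tables (for MAXENT only the active,
#' non-zero lasso terms); GAM returns per-smooth effective degrees of
#' freedom; BRT and RF return per-covariate split counts as a rough
#' importance indicator.
#'
#' @param x An `sdm_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sdm_model <- function(x, ...) {
  switch(x$algorithm$id,
    GLM = {
      cf <- stats::coef(x$fit$model)
      tibble(term = names(cf), estimate = as.numeric(cf))
    },
    GAM = {
      s <- summary(x$fit$model)
      tibble(term = rownames(s$s.table), edf = s$s.table[, "edf"])
    },
    MAXENT = {
      cf <- as.matrix(stats::coef(x$fit$model, s = "lambda.min"))
      nz <- cf[, 1] != 0
      tibble(term = rownames(cf)[nz], estimate = cf[nz, 1])
    },
    {
      counts <- table(factor(unlist(lapply(x$fit$trees, function(t)
        t$var[t$var >= 0] + 1L)), levels = seq_along(x$covariates)))
      tibble(term = x$covariates, n_splits = as.integer(counts))
    })
}

#' @rdname tidy.sdm_model
#' @export
glance.sdm_model <- function(x, ...) {
  tibble(algorithm = x$algorithm$id,
         n_presence = x$n_presence,
         n_background = x$n_background,
         n_covariates = length(x$covariates))
}
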