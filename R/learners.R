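#' Learner registry
#'
#' The ensemble is agnostic to its member algorithms: each family is an
#' entry in a registry mapping a name to a fit function and a
#' predict-probability function. The reference configuration registers the
#' nine families of the ensemble design — GBM (gradient-boosted trees,
#' xgboost), CTA (single classification tree, rpart), RF (random forest),
#' GLM (logistic regression), GAM (smooth additive logistic regression,
#' mgcv), ANN (single-hidden-layer perceptron, nnet), FDA (discriminant
#' analysis on spline features), MARS (spline-basis logistic regression)
#' and MAXENT (L1-regularized logistic regression on linear, quadratic and
#' pairwise-product features of the predictors — a documented approximation
#' to maximum-entropy modelling). Users can register further families with
#' [register_learner()].
#'
#' Class imbalance under the 10000-PA designs is handled by weighting the
#' presence class so its total weight equals the pseudo-absence total;
#' presence-matched designs are balanced already and get unit weights.
#'
#' @name learners
NULL

.learner_registry <- new.env(parent = emptyenv())

#' Register a learner family
#'
#' @param family family name (upper-cased key)
#' @param fit function(x, y, weights, seed, hyper) returning a model object;
#'   `x` is a numeric predictor matrix, `y` a 0/1 integer vector
#' @param predict function(fit, x) returning presence probabilities
#' @export
register_learner <- function(family, fit, predict) {
  stopifnot(is.function(fit), is.function(predict))
  assign(toupper(family), list(fit = fit, predict = predict),
         envir = .learner_registry)
  invisible(toupper(family))
}

#' Names of the registered learner families
#' @return character vector
#' @export
registered_learners <- function() sort(ls(.learner_registry))

get_learner <- function(family) {
  family <- toupper(family)
  if (!exists(family, envir = .learner_registry, inherits = FALSE))
    stop("unregistered learner family: ", family)
  get(family, envir = .learner_registry, inherits = FALSE)
}

# -- feature helpers ---------------------------------------------------------

# linear + quadratic + pairwise products, for the MAXENT approximation
quad_features <- function(x) {
  p <- ncol(x)
  out <- list(x, x^2)
  nm <- c(colnames(x), paste0(colnames(x), "_sq"))
  if (p >= 2) {
    pairs <- utils::combn(p, 2)
    prod_mat <- x[, pairs[1, ], drop = FALSE] * x[, pairs[2, ], drop = FALSE]
    colnames(prod_mat) <- paste0(colnames(x)[pairs[1, ]], "_x_",
                                 colnames(x)[pairs[2, ]])
    out <- c(out, list(prod_mat))
    nm <- c(nm, colnames(prod_mat))
  }
  m <- do.call(cbind, out)
  colnames(m) <- nm
  m
}

# natural-spline basis expansion of each column; falls back to the raw
# column when it has too few distinct values for the requested df
spline_features <- function(x, df = 3, knots = NULL) {
  cols <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    if (df <= 1) {
      b <- matrix(v, ncol = 1)
      attr(b, "knots") <- NULL
    } else if (!is.null(knots)) {
      if (is.null(knots[[j]]$boundary)) {
        b <- matrix(v, ncol = 1)
        attr(b, "knots") <- NULL
      } else {
        b <- splines::ns(v, knots = knots[[j]]$knots,
                         Boundary.knots = knots[[j]]$boundary)
      }
    } else if (length(unique(v)) > df) {
      b <- splines::ns(v, df = df)
    } else {
      b <- matrix(v, ncol = 1)
      attr(b, "knots") <- NULL
    }
    b
  })
  basis <- do.call(cbind, lapply(cols, unclass))
  colnames(basis) <- unlist(lapply(seq_along(cols), function(j)
    paste0(colnames(x)[j], "_s", seq_len(ncol(cols[[j]])))))
  attr(basis, "spline_spec") <- lapply(cols, function(b)
    list(knots = attr(b, "knots"), boundary = attr(b, "Boundary.knots")))
  basis
}

clamp01 <- function(p) pmin(1, pmax(0, p))

# -- built-in families -------------------------------------------------------

register_builtin_learners <- function() {
  register_learner("GLM",
    fit = function(x, y, weights, seed, hyper) {
      # BIC-stepwise term selection: with a handful of presences a full
      # linear model in all axes separates perfectly and memorizes
      d <- data.frame(.y = y, x)
      d$.w <- weights
      null_fit <- suppressWarnings(
        stats::glm(.y ~ 1, family = stats::binomial(), data = d,
                   weights = .w))
      scope <- stats::as.formula(paste("~", paste(colnames(x),
                                                  collapse = " + ")))
      suppressWarnings(stats::step(null_fit,
                                   scope = list(lower = ~1, upper = scope),
                                   direction = "both", trace = 0,
                                   k = hyper$k_penalty %||% log(nrow(d))))
    },
    predict = function(fit, x)
      clamp01(unname(stats::predict(fit, newdata = data.frame(x),
                                    type = "response"))))

  register_learner("GAM",
    fit = function(x, y, weights, seed, hyper) {
      k <- hyper$k %||% 4
      terms <- vapply(colnames(x), function(v) {
        if (length(unique(x[, v])) > k) sprintf("s(%s, k = %d)", v, k) else v
      }, character(1))
      d <- data.frame(.y = y, x)
      d$.w <- weights
      f <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
      # double-penalty shrinkage (select) so unsupported smooths drop out
      suppressWarnings(mgcv::gam(f, family = stats::binomial(), data = d,
                                 weights = .w, method = "REML",
                                 select = TRUE, gamma = hyper$gamma %||% 1.4))
    },
    predict = function(fit, x)
      clamp01(unname(mgcv::predict.gam(fit, newdata = data.frame(x),
                                       type = "response"))))

  register_learner("CTA",
    fit = function(x, y, weights, seed, hyper) {
      set.seed(seed)
      d <- data.frame(.y = factor(y, levels = c(0, 1)), x)
      rpart::rpart(.y ~ ., data = d, weights = weights, method = "class",
                   control = rpart::rpart.control(
                     minsplit = hyper$minsplit %||% 2,
                     minbucket = hyper$minbucket %||% 1,
                     cp = hyper$cp %||% 0.001,
                     xval = 0))
    },
    predict = function(fit, x)
      clamp01(unname(predict(fit, newdata = data.frame(x),
                             type = "prob")[, "1"])))

  register_learner("RF",
    fit = function(x, y, weights, seed, hyper) {
      set.seed(seed)
      randomForest::randomForest(x = x, y = factor(y, levels = c(0, 1)),
                                 ntree = hyper$ntree %||% 100)
    },
    predict = function(fit, x)
      clamp01(unname(predict(fit, newdata = x, type = "prob")[, "1"])))

  register_learner("GBM",
    fit = function(x, y, weights, seed, hyper) {
      xgboost::xgboost(data = x, label = y, weight = weights,
                       nrounds = hyper$nrounds %||% 30,
                       params = list(objective = "binary:logistic",
                                     max_depth = hyper$max_depth %||% 2,
                                     eta = hyper$eta %||% 0.1,
                                     nthread = 1, seed = seed),
                       verbose = 0)
    },
    predict = function(fit, x) clamp01(predict(fit, newdata = x)))

  register_learner("ANN",
    fit = function(x, y, weights, seed, hyper) {
      set.seed(seed)
      fit <- nnet::nnet(x = x, y = y, weights = weights,
                        size = hyper$size %||% 3,
                        decay = hyper$decay %||% 0.1,
                        maxit = hyper$maxit %||% 200,
                        entropy = TRUE, trace = FALSE)
      fit
    },
    predict = function(fit, x) clamp01(as.numeric(predict(fit, newdata = x))))

  register_learner("MARS",
    fit = function(x, y, weights, seed, hyper) {
      # spline-basis logistic regression; the L1 penalty plays the role of
      # the usual forward/backward basis pruning
      basis <- spline_features(x, df = hyper$df %||% 2)
      lam <- hyper$lambda %||% 0.01
      m <- glmnet::glmnet(basis, y, family = "binomial", alpha = 1,
                          weights = weights,
                          lambda = sort(unique(c(
                            exp(seq(log(1), log(lam), length.out = 20)), lam)),
                            decreasing = TRUE))
      list(glmnet = m, lambda = lam, spec = attr(basis, "spline_spec"),
           df = hyper$df %||% 2, vars = colnames(x))
    },
    predict = function(fit, x) {
      basis <- spline_features(x[, fit$vars, drop = FALSE], df = fit$df,
                               knots = fit$spec)
      clamp01(as.numeric(predict(fit$glmnet, newx = basis, s = fit$lambda,
                                 type = "response")))
    })

  register_learner("FDA",
    fit = function(x, y, weights, seed, hyper) {
      basis <- spline_features(x, df = hyper$df %||% 2)
      keep <- apply(basis, 2, function(v) stats::sd(v) > 0)
      m <- MASS::lda(x = basis[, keep, drop = FALSE],
                     grouping = factor(y, levels = c(0, 1)),
                     prior = c(0.5, 0.5))
      list(lda = m, spec = attr(basis, "spline_spec"), keep = keep,
           df = hyper$df %||% 2, vars = colnames(x))
    },
    predict = function(fit, x) {
      basis <- spline_features(x[, fit$vars, drop = FALSE], df = fit$df,
                               knots = fit$spec)
      p <- predict(fit$lda, newdata = basis[, fit$keep, drop = FALSE])
      clamp01(unname(p$posterior[, "1"]))
    })

  register_learner("MAXENT",
    fit = function(x, y, weights, seed, hyper) {
      feats <- quad_features(x)
      lam <- hyper$lambda %||% 0.01
      m <- glmnet::glmnet(feats, y, family = "binomial", alpha = 1,
                          weights = weights,
                          lambda = sort(unique(c(
                            exp(seq(log(1), log(lam), length.out = 25)), lam)),
                            decreasing = TRUE))
      list(glmnet = m, lambda = lam)
    },
    predict = function(fit, x) {
      feats <- quad_features(x)
      clamp01(as.numeric(predict(fit$glmnet, newx = feats, s = fit$lambda,
                                 type = "response")))
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.onLoad <- function(libname, pkgname) {
  register_builtin_learners()
}
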