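# Learner registry. Every learner works on a pre-standardized numeric
# predictor matrix and returns a fitted record:
#   list(kind = "linear"|"opaque", a = intercept, b = coefficient vector
#        (std scale, linear only), predict = function(z) (opaque only),
#        hyper = list of chosen hyperparameters)
# Regularized linear models and KNN are always usable; the remaining
# learners sit behind optional adapters and are skipped with a warning when
# their backing package is unavailable.

learner_names <- function() {
  c("intercept", "ridge", "lasso", "lasso_interactions", "mars", "svm_rbf",
    "knn", "gbdt_a", "gbdt_b", "nnet", "linear")
}

#' Describe a learner
#'
#' Returns the registry entry for one of the supported learning algorithms:
#' regularized linear regression (`ridge`, `lasso`, and `lasso_interactions`,
#' which additionally sees the planned interaction columns), `knn`,
#' `svm_rbf`, gradient-boosted trees (`gbdt_a` = xgboost; `gbdt_b` is a
#' second boosting adapter with no backing implementation here), a
#' single-layer neural network (`nnet`), multivariate adaptive regression
#' splines (`mars`, adapter only), an unpenalized `linear` model and the
#' `intercept`-only constant predictor used as baseline.
#'
#' @param name Learner name.
#' @return List with elements `name`, `available` (logical), `rank`
#'   (tie-break order, simpler first), `uses_interactions`, and the fitting
#'   function.
#' @export
learner_spec <- function(name) {
  if (!name %in% learner_names())
    stop_config("learner", paste("unknown learner:", name))
  spec <- list(name = name, uses_interactions = name == "lasso_interactions")
  spec$rank <- match(name, c("intercept", "linear", "ridge", "lasso",
                             "lasso_interactions", "knn", "mars", "svm_rbf",
                             "gbdt_a", "gbdt_b", "nnet"))
  spec$available <- switch(
    name,
    svm_rbf = requireNamespace("e1071", quietly = TRUE),
    gbdt_a = requireNamespace("xgboost", quietly = TRUE),
    nnet = requireNamespace("nnet", quietly = TRUE),
    knn = requireNamespace("caret", quietly = TRUE),
    mars = FALSE,  # no MARS backend shipped; adapter slot only
    gbdt_b = FALSE, # second boosting backend not bundled
    TRUE
  )
  spec
}

# ---- fitting on standardized predictors -------------------------------------

std_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}
std_apply <- function(x, st) sweep(sweep(x, 2, st$center), 2, st$scale, "/")

# deterministic fold ids
make_foldid <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

# fit one learner on standardized (z, y); hyper may be NULL => tune internally
fit_learner <- function(name, z, y, hyper = NULL, inner_folds = 5,
                        nlambda = 50, seed = 1) {
  switch(
    name,
    intercept = list(kind = "linear", a = mean(y),
                     b = setNames(rep(0, ncol(z)), colnames(z)), hyper = list()),
    linear = {
      df <- as.data.frame(z); df$.y <- y
      fit <- lm(.y ~ ., data = df)
      cf <- coef(fit); cf[is.na(cf)] <- 0
      list(kind = "linear", a = cf[1],
           b = setNames(cf[-1], colnames(z)), hyper = list())
    },
    ridge = fit_glmnet(z, y, alpha = 0, hyper, inner_folds, nlambda, seed),
    lasso = fit_glmnet(z, y, alpha = 1, hyper, inner_folds, nlambda, seed),
    lasso_interactions = fit_glmnet(z, y, alpha = 1, hyper, inner_folds, nlambda, seed),
    knn = fit_knn(z, y, hyper, inner_folds, seed),
    svm_rbf = fit_svm(z, y, hyper, inner_folds, seed),
    gbdt_a = fit_xgb(z, y, hyper, seed),
    nnet = fit_nnet(z, y, hyper, seed),
    stop_config("learner", paste(name, "has no backing implementation"))
  )
}

fit_glmnet <- function(z, y, alpha, hyper, inner_folds, nlambda, seed) {
  if (!is.null(hyper$lambda)) {
    fit <- glmnet::glmnet(z, y, alpha = alpha, lambda = hyper$lambda,
                          standardize = FALSE)
    cf <- as.numeric(coef(fit, s = hyper$lambda))
  } else {
    foldid <- make_foldid(length(y), max(3, inner_folds), seed)
    cv <- glmnet::cv.glmnet(z, y, alpha = alpha, foldid = foldid,
                            nlambda = nlambda, standardize = FALSE,
                            thresh = 1e-4)
    hyper <- list(lambda = cv$lambda.min)
    cf <- as.numeric(coef(cv, s = "lambda.min"))
  }
  list(kind = "linear", a = cf[1], b = setNames(cf[-1], colnames(z)),
       hyper = c(hyper, list(alpha = alpha)))
}

fit_knn <- function(z, y, hyper, inner_folds, seed) {
  grid <- if (is.null(hyper$k)) {
    ks <- unique(pmin(c(5L, 10L, 20L), max(2L, nrow(z) - 2L)))
    lapply(ks, function(k) list(k = k))
  } else list(hyper)
  hy <- tune_grid(grid, z, y, inner_folds, seed, function(zz, yy, h) {
    fit <- caret::knnreg(zz, yy, k = h$k)
    function(znew) predict(fit, as.data.frame(znew))
  })
  fit <- caret::knnreg(z, y, k = hy$k)
  list(kind = "opaque",
       predict = function(znew) predict(fit, as.data.frame(znew)),
       hyper = hy)
}

fit_svm <- function(z, y, hyper, inner_folds, seed) {
  grid <- if (is.null(hyper$cost)) lapply(c(1, 10), function(co) list(cost = co))
          else list(hyper)
  hy <- tune_grid(grid, z, y, inner_folds, seed, function(zz, yy, h) {
    fit <- e1071::svm(zz, yy, kernel = "radial", cost = h$cost)
    function(znew) as.numeric(predict(fit, znew))
  })
  fit <- e1071::svm(z, y, kernel = "radial", cost = hy$cost)
  list(kind = "opaque", predict = function(znew) as.numeric(predict(fit, znew)),
       hyper = hy)
}

fit_xgb <- function(z, y, hyper, seed) {
  hy <- hyper %||% list(nrounds = 150, eta = 0.05, max_depth = 3)
  set.seed(seed)
  fit <- xgboost::xgboost(
    data = z, label = y, nrounds = hy$nrounds,
    params = list(eta = hy$eta, max_depth = hy$max_depth, subsample = 0.8,
                  objective = "reg:squarederror"),
    verbose = 0, nthread = 1)
  list(kind = "opaque", predict = function(znew) predict(fit, znew), hyper = hy)
}

fit_nnet <- function(z, y, hyper, seed) {
  hy <- hyper %||% list(size = 5, decay = 0.1)
  set.seed(seed)
  # scale response into [0,1] for a logistic-output-free linear unit
  fit <- nnet::nnet(z, y, size = hy$size, decay = hy$decay, linout = TRUE,
                    maxit = 300, trace = FALSE)
  list(kind = "opaque", predict = function(znew) as.numeric(predict(fit, znew)),
       hyper = hy)
}

# small-grid hyperparameter tuning by k-fold CV RMSE on the training portion
tune_grid <- function(grid, z, y, folds, seed, fit_fun) {
  if (length(grid) == 1) return(grid[[1]])
  foldid <- make_foldid(length(y), max(2, min(folds, length(y) - 1)), seed)
  rmses <- vapply(grid, function(h) {
    errs <- lapply(unique(foldid), function(f) {
      tr <- foldid != f
      pr <- fit_fun(z[tr, , drop = FALSE], y[tr], h)(z[!tr, , drop = FALSE])
      y[!tr] - pr
    })
    sqrt(mean(unlist(errs)^2))
  }, numeric(1))
  grid[[which.min(rmses)]]
}

# prediction from a fitted record on *standardized* predictors
predict_record <- function(rec, z) {
  if (rec$kind == "linear") {
    if (!length(rec$b) || !ncol(z)) return(rep(as.numeric(rec$a), nrow(z)))
    as.numeric(rec$a + z %*% rec$b[colnames(z)])
  } else {
    as.numeric(rec$predict(z))
  }
}
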