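#' Classifier configuration
#'
#' Algorithms and default hyperparameters follow the conventional
#' settings for this task: kNN with 5 neighbours, uniform weights and
#' Minkowski (p = 2) distance; polynomial-kernel SVM with penalty C = 1;
#' XGBoost (learning rate 0.3, 650 estimators, depth 3) and LightGBM
#' (learning rate 0.1, 500 estimators, depth 2).  Only `knn` and `svm`
#' have backends in this package: no R ports of XGBoost/LightGBM are
#' available in the supported offline environment, so those configs are
#' accepted but training them raises a classed error.
#'
#' @param algorithm one of `"knn"`, `"svm"`, `"xgb"`, `"lgbm"`.
#' @param ... overrides of the per-algorithm defaults.
#' @param seed integer seed recorded in the fingerprint.
#' @return object of class `pd_classifier_config`.
#' @export
classifier_config <- function(algorithm = c("knn", "svm", "xgb", "lgbm"),
                              ..., seed = 1L) {
  algorithm <- tryCatch(match.arg(algorithm),
                        error = function(e)
                          pd_stop(sprintf("unknown algorithm '%s'", algorithm[1]),
                                  "pdmil_error_unknown_algorithm"))
  defaults <- switch(algorithm,
    knn = list(n_neighbors = 5L, weights = "uniform", p = 2),
    svm = list(kernel = "poly", C = 1, degree = 3L, coef0 = 1),
    xgb = list(learning_rate = 0.3, n_estimators = 650L, max_depth = 3L),
    lgbm = list(learning_rate = 0.1, n_estimators = 500L, max_depth = 2L))
  hp <- utils::modifyList(defaults, list(...))
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "pd_classifier_config")
}

#' Train a classifier on bag vectors
#'
#' @param config a [classifier_config()].
#' @param x numeric feature matrix (rows = bags).
#' @param y integer class labels.
#' @return fitted model of class `pd_model`.
#' @export
train_classifier <- function(config, x, y) {
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    pd_stop("training set has a single class", "pdmil_error_single_class")
  x <- as.matrix(x)
  fit <- switch(config$algorithm,
    knn = list(x = x, y = y),
    svm = svm_ovo_fit(x, y, config$hyperparameters),
    pd_stop(sprintf("no offline backend for algorithm '%s'", config$algorithm),
            "pdmil_error_backend_unavailable"))
  structure(list(config = config, fit = fit, classes = sort(unique(y))),
            class = "pd_model")
}

#' Predict class labels
#'
#' @param object a `pd_model`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return integer labels.
#' @export
predict.pd_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  switch(object$config$algorithm,
         knn = knn_predict(object$fit, newdata,
                           object$config$hyperparameters),
         svm = svm_ovo_predict(object$fit, newdata))
}

# deterministic kNN: Minkowski-p distance, uniform vote, distance then
# lowest-class tie-break
knn_predict <- function(fit, newdata, hp) {
  k <- min(hp$n_neighbors, nrow(fit$x))
  p <- hp$p %||% 2
  apply(newdata, 1, function(q) {
    d <- if (p == 2) sqrt(rowSums(sweep(fit$x, 2, q)^2))
    else rowSums(abs(sweep(fit$x, 2, q))^p)^(1 / p)
    ord <- order(d, fit$y)
    votes <- tabulate(fit$y[ord[seq_len(k)]] + 1L,
                      nbins = max(fit$y) + 1L)
    which.max(votes) - 1L     # ties -> lowest class id
  })
}

# one-vs-one soft-margin SVM via the dual QP (quadprog); features are
# standardized internally, kernel (gamma <x,z> + coef0)^degree
svm_ovo_fit <- function(x, y, hp) {
  mu <- colMeans(x)
  sdev <- matrixStats::colSds(x)
  sdev[sdev == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdev, "/")
  gamma <- 1 / ncol(x)
  classes <- sort(unique(y))
  machines <- list()
  for (i in seq_along(classes)) for (j in seq_along(classes)) {
    if (i >= j) next
    idx <- y %in% classes[c(i, j)]
    xi <- xs[idx, , drop = FALSE]
    yi <- ifelse(y[idx] == classes[i], 1, -1)
    K <- (gamma * tcrossprod(xi) + hp$coef0)^hp$degree
    n <- nrow(xi)
    Dmat <- (yi %o% yi) * K + diag(1e-8, n)
    Amat <- cbind(yi, diag(n), -diag(n))
    bvec <- c(0, rep(0, n), rep(-hp$C, n))
    sol <- quadprog::solve.QP(Dmat, rep(1, n), Amat, bvec, meq = 1)
    a <- pmax(sol$solution, 0)
    sv <- a > 1e-8
    free <- sv & a < hp$C - 1e-8
    fsv <- if (any(free)) which(free) else which(sv)
    b <- mean(yi[fsv] - colSums((a * yi) * K)[fsv])
    machines[[paste(classes[i], classes[j], sep = "_")]] <-
      list(pos = classes[i], neg = classes[j], alpha = a[sv],
           ysv = yi[sv], xsv = xi[sv, , drop = FALSE], b = b)
  }
  list(machines = machines, mu = mu, sd = sdev, gamma = gamma,
       degree = hp$degree, coef0 = hp$coef0, classes = classes)
}

svm_ovo_predict <- function(fit, newdata) {
  xs <- sweep(sweep(newdata, 2, fit$mu), 2, fit$sd, "/")
  votes <- matrix(0, nrow(xs), max(fit$classes) + 1L)
  for (m in fit$machines) {
    K <- (fit$gamma * xs %*% t(m$xsv) + fit$coef0)^fit$degree
    f <- as.numeric(K %*% (m$alpha * m$ysv)) + m$b
    win <- ifelse(f >= 0, m$pos, m$neg)
    for (r in seq_along(win)) votes[r, win[r] + 1L] <- votes[r, win[r] + 1L] + 1
  }
  apply(votes, 1, which.max) - 1L
}
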