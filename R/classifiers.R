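#' Classifier specification
#'
#' A classifier family plus a hyperparameter setting drawn from the tuning
#' ranges of the evaluation protocol (see [table2_grid()] for the ranges and
#' their discretization).
#'
#' @param family One of `"knn"`, `"svm"`, `"lda"`, `"ann"`, `"rf"`, `"lr"`.
#' @param ... Named hyperparameters; unset ones take the family defaults.
#' @return A `model_spec`.
#' @export
model_spec <- function(family = c("knn", "svm", "lda", "ann", "rf", "lr"), ...) {
  family <- match.arg(family)
  params <- list(...)
  defaults <- switch(family,
    knn = list(distance = "euclidean", weights = "equal", exponent = 2,
               neighbors = 2L),
    # kernel_scale NULL = set to sqrt(n_features) at fit time (the usual
    # "auto" heuristic for standardized inputs)
    svm = list(kernel = "gaussian", box_constraint = 1, kernel_scale = NA_real_,
               poly_order = 2L),
    lda = list(gamma = 0, delta = 0, discrim_type = "linear"),
    # weight decay sized for ~10^2 features per ~10^2 training epochs
    ann = list(activation = "tanh", hidden = 50L, weight_decay = 1e-3,
               max_epochs = 1000L, patience = 50L, lr = 1e-3,
               batch_size = 16L),
    rf = list(n_trees = 50L, depth = 10L),
    lr = list(penalty = "L2", C = 1)
  )
  bad <- setdiff(names(params), names(defaults))
  if (length(bad)) {
    abort_value(sprintf("unknown hyperparameter(s) for %s: %s", family,
                        paste(bad, collapse = ", ")))
  }
  validate_spec_params(family, utils::modifyList(defaults, params))
  structure(list(family = family, params = utils::modifyList(defaults, params)),
            class = "model_spec")
}

knn_distances <- function() {
  c("cityblock", "chebychev", "correlation", "cosine", "euclidean", "hamming",
    "jaccard", "mahalanobis", "minkowski", "spearman")
}

validate_spec_params <- function(family, p) {
  chk <- function(ok, msg) if (!ok) abort_value(msg)
  switch(family,
    knn = {
      chk(p$distance %in% knn_distances(), "invalid kNN distance")
      chk(p$weights %in% c("equal", "inverse", "squaredinverse"),
          "invalid kNN distance weighting")
      chk(p$exponent >= 0.5 && p$exponent <= 3, "kNN exponent outside [0.5, 3]")
      chk(p$neighbors >= 1 && p$neighbors <= 5, "kNN neighbors outside [1, 5]")
    },
    svm = {
      chk(p$kernel %in% c("gaussian", "linear", "polynomial"),
          "invalid SVM kernel")
      chk(p$box_constraint >= 1e-3 && p$box_constraint <= 1e3,
          "SVM box constraint outside [1e-3, 1e3]")
      chk(is.na(p$kernel_scale) ||
            (p$kernel_scale >= 1e-3 && p$kernel_scale <= 1e3),
          "SVM kernel scale outside [1e-3, 1e3]")
      chk(p$poly_order %in% 2:4, "SVM polynomial order must be 2, 3 or 4")
    },
    lda = {
      chk(p$gamma >= 0 && p$gamma <= 1, "LDA gamma outside [0, 1]")
      chk(p$delta >= 0 && p$delta <= 1e3, "LDA delta outside [0, 1e3]")
      chk(p$discrim_type %in% c("linear", "quadratic", "diagLinear",
                                "diagQuadratic", "pseudoLinear",
                                "pseudoQuadratic"),
          "invalid LDA discriminant type")
    },
    ann = {
      chk(p$activation %in% c("relu", "sigmoid", "tanh"),
          "invalid ANN activation")
      chk(p$hidden >= 25 && p$hidden <= 200, "ANN hidden neurons outside [25, 200]")
    },
    rf = {
      chk(p$n_trees >= 15 && p$n_trees <= 100, "RF trees outside [15, 100]")
      chk(p$depth >= 5 && p$depth <= 30, "RF depth outside [5, 30]")
    },
    lr = {
      chk(p$penalty %in% c("L2", "elasticnet"), "invalid LR penalty")
      chk(p$C >= 0.25 && p$C <= 1.0, "LR C outside [0.25, 1.0]")
    }
  )
  invisible(p)
}

#' Hyperparameter grids of the evaluation protocol
#'
#' Returns the tuning grid for one classifier family: categorical ranges are
#' enumerated, continuous ranges discretized on linear or log grids of
#' `n_points` values.
#'
#' @param family Classifier family.
#' @param n_points Points per continuous range.
#' @return A tibble, one row per hyperparameter setting.
#' @export
table2_grid <- function(family = c("knn", "svm", "lda", "ann", "rf", "lr"),
                        n_points = 5L) {
  family <- match.arg(family)
  lin <- function(a, b) seq(a, b, length.out = n_points)
  logg <- function(a, b) exp(seq(log(a), log(b), length.out = n_points))
  g <- switch(family,
    knn = expand.grid(distance = knn_distances(),
                      weights = c("equal", "inverse", "squaredinverse"),
                      exponent = lin(0.5, 3), neighbors = 1:5,
                      stringsAsFactors = FALSE),
    svm = {
      gg <- expand.grid(kernel = c("gaussian", "linear", "polynomial"),
                        box_constraint = logg(1e-3, 1e3),
                        kernel_scale = logg(1e-3, 1e3),
                        poly_order = 2:4, stringsAsFactors = FALSE)
      # order only meaningful for the polynomial kernel
      gg[gg$kernel == "polynomial" | gg$poly_order == 2L, ]
    },
    lda = expand.grid(gamma = lin(0, 1), delta = logg(1e-6, 1e3),
                      discrim_type = c("linear", "quadratic", "diagLinear",
                                       "diagQuadratic", "pseudoLinear",
                                       "pseudoQuadratic"),
                      stringsAsFactors = FALSE),
    ann = expand.grid(activation = c("relu", "sigmoid", "tanh"),
                      hidden = as.integer(round(lin(25, 200))),
                      stringsAsFactors = FALSE),
    rf = expand.grid(n_trees = as.integer(round(lin(15, 100))),
                     depth = as.integer(round(lin(5, 30)))),
    lr = expand.grid(penalty = c("L2", "elasticnet"), C = lin(0.25, 1),
                     stringsAsFactors = FALSE)
  )
  tibble::as_tibble(g)
}

# ---- kNN over explicit distance matrices --------------------------------

knn_dist_matrix <- function(test, train, distance, exponent = 2, S_inv = NULL) {
  switch(distance,
    euclidean = sqrt(pmax(outer(rowSums(test^2), rowSums(train^2), "+") -
                            2 * tcrossprod(test, train), 0)),
    cityblock = apply(train, 1, function(tr) colSums(abs(t(test) - tr))),
    chebychev = apply(train, 1, function(tr) apply(abs(sweep(test, 2, tr)), 1, max)),
    minkowski = apply(train, 1, function(tr) {
      colSums(abs(t(test) - tr)^exponent)^(1 / exponent)
    }),
    cosine = {
      nt <- sqrt(rowSums(test^2)); nr <- sqrt(rowSums(train^2))
      1 - tcrossprod(test, train) / outer(pmax(nt, 1e-300), pmax(nr, 1e-300))
    },
    correlation = {
      tc <- test - rowMeans(test); rc <- train - rowMeans(train)
      nt <- sqrt(rowSums(tc^2)); nr <- sqrt(rowSums(rc^2))
      1 - tcrossprod(tc, rc) / outer(pmax(nt, 1e-300), pmax(nr, 1e-300))
    },
    spearman = {
      tr_r <- t(apply(test, 1, rank)); rr <- t(apply(train, 1, rank))
      tc <- tr_r - rowMeans(tr_r); rc <- rr - rowMeans(rr)
      nt <- sqrt(rowSums(tc^2)); nr <- sqrt(rowSums(rc^2))
      1 - tcrossprod(tc, rc) / outer(pmax(nt, 1e-300), pmax(nr, 1e-300))
    },
    hamming = apply(train, 1, function(tr) colMeans(t(test) != tr)),
    jaccard = apply(train, 1, function(tr) {
      tt <- t(test)
      nz <- (tt != 0) | (tr != 0)
      colSums((tt != tr) & nz) / pmax(colSums(nz), 1)
    }),
    mahalanobis = {
      L <- t(chol(S_inv))
      tw <- test %*% L; rw <- train %*% L
      sqrt(pmax(outer(rowSums(tw^2), rowSums(rw^2), "+") -
                  2 * tcrossprod(tw, rw), 0))
    },
    abort_value(sprintf("unknown distance: %s", distance))
  )
}

fit_knn <- function(X, y, params) {
  S_inv <- NULL
  if (params$distance == "mahalanobis") {
    S <- stats::cov(X)
    S <- S + diag(1e-6 * mean(diag(S)) + 1e-12, ncol(X))
    S_inv <- solve(S)
  }
  structure(list(X = X, y = as.character(y), params = params, S_inv = S_inv,
                 levels = sort(unique(as.character(y)))),
            class = "knn_model")
}

#' @export
predict.knn_model <- function(object, newdata, ...) {
  p <- object$params
  D <- knn_dist_matrix(newdata, object$X, p$distance, p$exponent, object$S_inv)
  k <- min(p$neighbors, nrow(object$X))
  out <- character(nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    ord <- order(D[i, ])[1:k]
    d <- D[i, ord]
    w <- switch(p$weights,
      equal = rep(1, k),
      inverse = 1 / pmax(d, 1e-12),
      squaredinverse = 1 / pmax(d, 1e-12)^2
    )
    votes <- tapply(w, factor(object$y[ord], levels = object$levels), sum,
                    default = 0)
    best <- which(votes == max(votes))
    if (length(best) > 1L) {
      # tie: class of the single nearest neighbour
      out[i] <- object$y[ord[1]]
    } else {
      out[i] <- names(votes)[best]
    }
  }
  factor(out, levels = object$levels)
}

# ---- Regularized discriminant analysis ----------------------------------

rda_class_stats <- function(X, y, type, gamma) {
  lev <- sort(unique(as.character(y)))
  p <- ncol(X)
  mu <- lapply(lev, function(l) colMeans(X[y == l, , drop = FALSE]))
  covs <- lapply(lev, function(l) stats::cov(X[y == l, , drop = FALSE]))
  pooled <- Reduce(`+`, lapply(seq_along(lev), function(i) {
    covs[[i]] * (sum(y == lev[i]) - 1)
  })) / (nrow(X) - length(lev))
  shrink <- function(S) {
    if (grepl("diag", type, ignore.case = TRUE)) S <- diag(diag(S), p)
    (1 - gamma) * S + gamma * mean(diag(S)) * diag(p)
  }
  quadratic <- grepl("uadratic", type)
  pseudo <- grepl("pseudo", type, ignore.case = TRUE)
  inv <- function(S) {
    if (pseudo) MASS::ginv(S) else {
      tryCatch(solve(S), error = function(e) MASS::ginv(S))
    }
  }
  list(levels = lev, mu = mu,
       S = if (quadratic) lapply(covs, shrink) else shrink(pooled),
       quadratic = quadratic, inv = inv)
}

fit_rlda <- function(X, y, params) {
  st <- rda_class_stats(X, y, params$discrim_type, params$gamma)
  if (st$quadratic) {
    Sinv <- lapply(st$S, st$inv)
    logdet <- vapply(st$S, function(S) {
      determinant(S, logarithm = TRUE)$modulus[1]
    }, 0)
    mdl <- list(levels = st$levels, mu = st$mu, Sinv = Sinv, logdet = logdet,
                quadratic = TRUE)
  } else {
    Sinv <- st$inv(st$S)
    w <- Sinv %*% (st$mu[[1]] - st$mu[[2]])
    if (params$delta > 0) w[abs(w) < params$delta] <- 0
    b <- -0.5 * sum((st$mu[[1]] + st$mu[[2]]) * w)
    mdl <- list(levels = st$levels, w = as.numeric(w), b = b, quadratic = FALSE)
  }
  structure(mdl, class = "rlda_model")
}

#' @export
predict.rlda_model <- function(object, newdata, ...) {
  if (object$quadratic) {
    sc <- vapply(1:2, function(i) {
      d <- sweep(newdata, 2, object$mu[[i]])
      -0.5 * rowSums((d %*% object$Sinv[[i]]) * d) - 0.5 * object$logdet[i]
    }, numeric(nrow(newdata)))
    idx <- apply(matrix(sc, ncol = 2), 1, which.max)
    factor(object$levels[idx], levels = object$levels)
  } else {
    s <- as.numeric(newdata %*% object$w) + object$b
    factor(ifelse(s > 0, object$levels[1], object$levels[2]),
           levels = object$levels)
  }
}

# ---- Unified fit / predict dispatch -------------------------------------

#' Fit a classifier from a model specification
#'
#' @param spec A [model_spec()].
#' @param X Training feature matrix.
#' @param y Training labels (two classes).
#' @param validation_idx Validation rows (ANN only).
#' @param seed RNG seed for stochastic learners.
#' @return A fitted model; use [predict_model()] on new data.
#' @export
fit_model <- function(spec, X, y, validation_idx = NULL, seed = 1L) {
  p <- spec$params
  y <- as.character(y)
  switch(spec$family,
    knn = fit_knn(X, y, p),
    svm = {
      ks <- if (is.na(p$kernel_scale)) sqrt(ncol(X)) else p$kernel_scale
      args <- list(x = X, y = factor(y), scale = FALSE, cost = p$box_constraint)
      if (p$kernel == "gaussian") {
        args$kernel <- "radial"; args$gamma <- 1 / ks^2
      } else if (p$kernel == "linear") {
        args$kernel <- "linear"
      } else {
        args$kernel <- "polynomial"; args$degree <- p$poly_order
        args$gamma <- 1 / ks^2; args$coef0 <- 1
      }
      with_seed(seed, do.call(e1071::svm, args))
    },
    lda = fit_rlda(X, y, p),
    ann = {
      if (is.null(validation_idx)) {
        abort_value("ANN training requires `validation_idx`")
      }
      train_ann(X, y, hidden = p$hidden, activation = p$activation,
                validation_idx = validation_idx, seed = seed,
                max_epochs = p$max_epochs, patience = p$patience,
                weight_decay = p$weight_decay, lr = p$lr,
                batch_size = p$batch_size)
    },
    rf = with_seed(seed, randomForest::randomForest(
      x = X, y = factor(y), ntree = p$n_trees,
      maxnodes = min(2L^p$depth, sum(!is.na(y)))
    )),
    lr = {
      alpha <- if (p$penalty == "L2") 0 else 0.5
      lam <- 1 / (p$C * nrow(X))
      fit <- glmnet::glmnet(X, factor(y), family = "binomial", alpha = alpha,
                            lambda = lam, standardize = FALSE)
      structure(list(fit = fit, levels = sort(unique(y)), lambda = lam),
                class = "lr_model")
    }
  )
}

#' @export
predict.lr_model <- function(object, newdata, ...) {
  pr <- stats::predict(object$fit, newx = newdata, s = object$lambda,
                       type = "response")
  factor(ifelse(as.numeric(pr) > 0.5, object$levels[2], object$levels[1]),
         levels = object$levels)
}

#' Predict classes from any fitted classifier
#' @param model A model returned by [fit_model()].
#' @param newdata Feature matrix.
#' @return Factor of predicted labels.
#' @export
predict_model <- function(model, newdata) {
  if (inherits(model, "svm")) {
    stats::predict(model, newdata)
  } else {
    stats::predict(model, newdata)
  }
}
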