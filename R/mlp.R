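# Small fully connected neural network classifier (3 layers: two ReLU hidden
# layers and a 2-unit softmax output), trained with mini-batch Adam, inverted
# dropout after each hidden activation, and an L2 weight-decay penalty added
# to the gradients of all parameters. Written in base R matrix code; the
# network sizes used here (tens to hundreds of hidden units) train in
# seconds per fit.

#' Three-layer MLP architecture from the first hidden-layer size
#'
#' The second hidden layer has half the units of the first, rounded up to
#' the nearest integer; the output layer has one unit per class (2).
#'
#' @param hidden1 First hidden-layer size, >= 1.
#' @return An `mlp_architecture` list: `hidden1`, `hidden2`, `output`,
#'   `activation`.
#' @export
build_mlp <- function(hidden1) {
  if (!is_count(hidden1)) stop_config("hidden1 must be a positive integer")
  structure(list(hidden1 = as.integer(hidden1),
                 hidden2 = as.integer(ceiling(hidden1 / 2)),
                 output = 2L, activation = "relu"),
            class = "mlp_architecture")
}

#' Hidden-layer-size regularization axis
#' @return The ordered sizes `{1, 2, 3, 4, 5, 10, 50, 100, 500, 1000}`.
#' @export
hidden_size_axis <- function() c(1L, 2L, 3L, 4L, 5L, 10L, 50L, 100L, 500L, 1000L)

#' Dropout-proportion regularization axis
#' @return The ordered dropout proportions swept when dropout is the
#'   regularization axis.
#' @export
dropout_axis <- function() {
  c(0.0, 0.05, 0.125, 0.25, 0.375, 0.5, 0.625, 0.75, 0.875, 0.95)
}

#' Weight-decay regularization axis
#' @return The ordered weight-decay (L2) values swept when weight decay is
#'   the regularization axis.
#' @export
weight_decay_axis <- function() {
  c(0.0, 0.001, 0.005, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.75, 1.0, 10.0)
}

#' Training protocol for the MLP
#'
#' @param epochs Training epochs (100).
#' @param batch_size Mini-batch size (50).
#' @param search_budget Random-search combinations for hyperparameter tuning
#'   (10).
#' @param learning_rates,dropouts,weight_decays Search grids for the tuned
#'   hyperparameters.
#' @return A `training_protocol` list.
#' @export
training_protocol <- function(epochs = 100L, batch_size = 50L,
                              search_budget = 10L,
                              learning_rates = c(0.1, 0.01, 0.001, 5e-4, 1e-4),
                              dropouts = c(0.1, 0.5, 0.75),
                              weight_decays = c(0, 0.1, 1, 10, 100)) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 search_budget = as.integer(search_budget),
                 learning_rates = learning_rates, dropouts = dropouts,
                 weight_decays = weight_decays),
            class = "training_protocol")
}

relu <- function(x) x * (x > 0)

# Stratified mini-batch assignment: per class, shuffled indices are dealt
# round-robin over batches so every batch keeps roughly the class mix.
stratified_batches <- function(y, batch_size) {
  n_batches <- max(1L, ceiling(length(y) / batch_size))
  batch <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    batch[idx] <- rep_len(sample.int(n_batches), length(idx))
  }
  split(seq_along(y), batch)
}

#' Train the 3-layer MLP classifier
#'
#' Cross-entropy loss over the 2-unit softmax output; exactly `epochs`
#' passes (no early stopping); Adam updates with the L2 weight-decay term
#' added to every parameter's gradient; inverted dropout after each hidden
#' ReLU during training only.
#'
#' @param X Standardized samples x features matrix.
#' @param y Binary 0/1 labels, both classes present.
#' @param hidden1 First hidden-layer size (see [build_mlp()]).
#' @param learning_rate,dropout,weight_decay Tuned hyperparameters.
#' @param protocol A [training_protocol()].
#' @param seed Integer seed controlling initialization, batching, dropout.
#' @return An `mlp_model` with a [predict][predict.mlp_model] method
#'   returning positive-class probabilities.
#' @export
train_mlp <- function(X, y, hidden1, learning_rate, dropout, weight_decay,
                      protocol = training_protocol(), seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) single_class_error("train_mlp")
  arch <- build_mlp(hidden1)
  p <- ncol(X)
  with_seed(seed, {
    dims <- list(c(p, arch$hidden1), c(arch$hidden1, arch$hidden2),
                 c(arch$hidden2, arch$output))
    W <- lapply(dims, function(d) {
      matrix(rnorm(d[1L] * d[2L], sd = sqrt(2 / d[1L])), d[1L], d[2L])
    })
    b <- lapply(dims, function(d) numeric(d[2L]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_step <- 0L
    Y <- cbind(1 - y, y) # one-hot: column 2 = positive class
    for (epoch in seq_len(protocol$epochs)) {
      for (idx in stratified_batches(y, protocol$batch_size)) {
        xb <- X[idx, , drop = FALSE]
        yb <- Y[idx, , drop = FALSE]
        nb <- length(idx)
        # forward
        z1 <- sweep(xb %*% W[[1L]], 2L, b[[1L]], "+"); a1 <- relu(z1)
        if (dropout > 0) {
          m1 <- matrix(runif(length(a1)) >= dropout, nrow(a1)) / (1 - dropout)
          a1 <- a1 * m1
        }
        z2 <- sweep(a1 %*% W[[2L]], 2L, b[[2L]], "+"); a2 <- relu(z2)
        if (dropout > 0) {
          m2 <- matrix(runif(length(a2)) >= dropout, nrow(a2)) / (1 - dropout)
          a2 <- a2 * m2
        }
        z3 <- sweep(a2 %*% W[[3L]], 2L, b[[3L]], "+")
        z3 <- z3 - apply(z3, 1L, max)
        probs <- exp(z3) / rowSums(exp(z3))
        if (any(!is.finite(probs))) {
          stop(rlang::error_cnd("mutbench_divergence_error",
                                message = "non-finite loss during MLP training"))
        }
        # backward (mean cross-entropy over the batch)
        d3 <- (probs - yb) / nb
        gW3 <- crossprod(a2, d3); gb3 <- colSums(d3)
        da2 <- tcrossprod(d3, W[[3L]])
        if (dropout > 0) da2 <- da2 * m2
        d2 <- da2 * (z2 > 0)
        gW2 <- crossprod(a1, d2); gb2 <- colSums(d2)
        da1 <- tcrossprod(d2, W[[2L]])
        if (dropout > 0) da1 <- da1 * m1
        d1 <- da1 * (z1 > 0)
        gW1 <- crossprod(xb, d1); gb1 <- colSums(d1)
        gW <- list(gW1, gW2, gW3); gb <- list(gb1, gb2, gb3)
        t_step <- t_step + 1L
        for (l in 1:3) {
          gw <- gW[[l]] + weight_decay * W[[l]]
          gbl <- gb[[l]] + weight_decay * b[[l]]
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gw
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gw^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gbl
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gbl^2
          mh <- mW[[l]] / (1 - beta1^t_step)
          vh <- vW[[l]] / (1 - beta2^t_step)
          W[[l]] <- W[[l]] - learning_rate * mh / (sqrt(vh) + eps)
          mhb <- mb[[l]] / (1 - beta1^t_step)
          vhb <- vb[[l]] / (1 - beta2^t_step)
          b[[l]] <- b[[l]] - learning_rate * mhb / (sqrt(vhb) + eps)
        }
      }
    }
    structure(list(W = W, b = b, architecture = arch,
                   hyperparameters = list(learning_rate = learning_rate,
                                          dropout = dropout,
                                          weight_decay = weight_decay),
                   features = colnames(X)),
              class = "mlp_model")
  })
}

#' @export
predict.mlp_model <- function(object, newdata, ...) {
  x <- newdata[, object$features, drop = FALSE]
  a1 <- relu(sweep(x %*% object$W[[1L]], 2L, object$b[[1L]], "+"))
  a2 <- relu(sweep(a1 %*% object$W[[2L]], 2L, object$b[[2L]], "+"))
  z3 <- sweep(a2 %*% object$W[[3L]], 2L, object$b[[3L]], "+")
  z3 <- z3 - apply(z3, 1L, max)
  probs <- exp(z3) / rowSums(exp(z3))
  setNames(probs[, 2L], rownames(x))
}

#' Random-search hyperparameter tuning for the MLP
#'
#' Evaluates `search_budget` distinct random combinations from the printed
#' hyperparameter grids on a single train/holdout split stratified by cancer
#' type (and label), returning the combination with the best holdout AUPR.
#' Ties are broken toward larger weight decay, then lower learning rate.
#'
#' @param X,y Standardized features and labels for the training context.
#' @param cancer_types Per-sample cancer types for stratification (named by
#'   sample or aligned to rows of `X`).
#' @param hidden1 Fixed first hidden-layer size, or `NULL` to include hidden
#'   size in the search (used when dropout or weight decay is the sweep
#'   axis).
#' @param fixed Named list of hyperparameters held fixed (excluded from the
#'   search), e.g. `list(dropout = 0.5)` when dropout is the sweep axis.
#' @param protocol A [training_protocol()].
#' @param seed Search seed.
#' @return List with the selected `learning_rate`, `dropout`,
#'   `weight_decay`, `hidden1`, and the search `results` tibble.
#' @export
tune_hyperparameters <- function(X, y, cancer_types, hidden1 = NULL,
                                 fixed = list(), protocol = training_protocol(),
                                 seed = 1L) {
  grid <- expand.grid(
    learning_rate = if (is.null(fixed$learning_rate)) protocol$learning_rates else fixed$learning_rate,
    dropout = if (is.null(fixed$dropout)) protocol$dropouts else fixed$dropout,
    weight_decay = if (is.null(fixed$weight_decay)) protocol$weight_decays else fixed$weight_decay,
    hidden1 = if (is.null(hidden1)) hidden_size_axis() else hidden1,
    KEEP.OUT.ATTRS = FALSE)
  budget <- min(protocol$search_budget, nrow(grid))
  with_seed(seed, {
    combos <- grid[sample.int(nrow(grid), budget), , drop = FALSE]
    strata <- paste(cancer_types, y, sep = "|")
    hold <- unlist(lapply(split(seq_along(y), strata), function(idx) {
      idx[sample.int(length(idx))][seq_len(max(1L, round(length(idx) / 4)))]
    }), use.names = FALSE)
    tr <- setdiff(seq_along(y), hold)
    auprs <- vapply(seq_len(nrow(combos)), function(i) {
      cmb <- combos[i, ]
      fit <- tryCatch(
        train_mlp(X[tr, , drop = FALSE], y[tr], cmb$hidden1,
                  cmb$learning_rate, cmb$dropout, cmb$weight_decay,
                  protocol, seed = seed + i),
        mutbench_divergence_error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      sc <- predict(fit, X[hold, , drop = FALSE])
      if (length(unique(y[hold])) < 2L) return(NA_real_)
      aupr(sc, y[hold])
    }, numeric(1))
    if (all(is.na(auprs))) {
      stop_data("no hyperparameter combination trained successfully")
    }
    results <- tibble::as_tibble(cbind(combos, holdout_aupr = auprs))
    ord <- order(-results$holdout_aupr, -results$weight_decay,
                 results$learning_rate)
    best <- results[ord[1L], ]
    list(learning_rate = best$learning_rate, dropout = best$dropout,
         weight_decay = best$weight_decay, hidden1 = best$hidden1,
         results = results)
  })
}

#' Sweep an MLP regularization axis over cross-validation splits
#'
#' Varies one of hidden-layer size, dropout proportion, or weight decay as
#' the regularization axis, recording train/holdout/test AUPR per (axis
#' value, fold) with one refolding seed and 4 folds (4 measurements per
#' value). Remaining hyperparameters are either supplied fixed via
#' `hyperparameters` or tuned once per axis value by random search
#' (including hidden size when it is not the axis).
#'
#' @param block A [build_features()] block.
#' @param splits A [make_splits()] assignment (build with `n_seeds = 1`).
#' @param axis `"hidden_size"`, `"dropout"`, or `"weight_decay"`.
#' @param axis_values Values to sweep; defaults to the axis's printed grid.
#' @param hyperparameters Optional named list (`learning_rate`, `dropout`,
#'   `weight_decay`, `hidden1` as applicable) fixing the non-axis
#'   hyperparameters and skipping tuning.
#' @param protocol A [training_protocol()].
#' @param cancer_types Per-sample cancer types (needed when tuning).
#' @param gene,context Identifiers copied into the result rows.
#' @param seed Base seed for training runs.
#' @return A `sweep_result` tibble in the same tidy layout as
#'   [run_linear_sweep()], with `axis` naming the swept hyperparameter and
#'   weight norms in `l1_norm`/`l2_norm` (`nonzero_count` is `NA` for
#'   networks). Divergent fits are recorded with `NA` AUPR.
#' @export
run_mlp_sweep <- function(block, splits,
                          axis = c("hidden_size", "dropout", "weight_decay"),
                          axis_values = NULL, hyperparameters = NULL,
                          protocol = training_protocol(),
                          cancer_types = NULL,
                          gene = "target", context = "test", seed = 1L) {
  axis <- match.arg(axis)
  axis_values <- axis_values %||% switch(axis,
    hidden_size = hidden_size_axis(),
    dropout = dropout_axis(),
    weight_decay = weight_decay_axis())
  design <- splits$design
  test_ids <- intersect(splits$test_ids, rownames(block$X))
  rows <- list()
  for (v_i in seq_along(axis_values)) {
    v <- axis_values[[v_i]]
    hp <- hyperparameters
    if (is.null(hp)) {
      pool_ids <- splits$folds$sample_id[splits$folds$seed == 1L]
      std_all <- standardize_features(block$X, pool_ids)
      fixed <- switch(axis, hidden_size = list(),
                      dropout = list(dropout = v),
                      weight_decay = list(weight_decay = v))
      hp <- tune_hyperparameters(
        std_all$X[pool_ids, , drop = FALSE], block$y[pool_ids],
        cancer_types[pool_ids],
        hidden1 = if (axis == "hidden_size") v else NULL,
        fixed = fixed, protocol = protocol, seed = seed + v_i)
    }
    hidden1 <- if (axis == "hidden_size") v else hp$hidden1 %||% 50L
    dropout <- if (axis == "dropout") v else hp$dropout
    wd <- if (axis == "weight_decay") v else hp$weight_decay
    for (s in seq_len(design$n_seeds)) {
      for (f in seq_len(design$n_folds)) {
        m <- split_members(splits, s, f)
        if (length(unique(block$y[m$train])) < 2L) next
        std <- standardize_features(block$X, m$train)
        fit <- tryCatch(
          train_mlp(std$X[m$train, , drop = FALSE], block$y[m$train],
                    hidden1, hp$learning_rate, dropout, wd, protocol,
                    seed = seed + 97L * v_i + 13L * f + s),
          mutbench_divergence_error = function(e) NULL)
        wnorm1 <- if (is.null(fit)) NA_real_ else sum(abs(unlist(fit$W)))
        wnorm2 <- if (is.null(fit)) NA_real_ else sqrt(sum(unlist(fit$W)^2))
        for (role in c("train", "holdout", "test")) {
          ids <- switch(role, train = m$train, holdout = m$holdout,
                        test = test_ids)
          yv <- block$y[ids]
          prev <- mean(yv)
          a <- if (!is.null(fit) && prev > 0 && prev < 1) {
            aupr(predict(fit, std$X[ids, , drop = FALSE]), yv)
          } else NA_real_
          rows[[length(rows) + 1L]] <- tibble::tibble(
            gene = gene, context = context, axis = axis, param = v,
            seed = s, fold = f, role = role, aupr = a, prevalence = prev,
            nonzero_count = NA_integer_, l1_norm = wnorm1, l2_norm = wnorm2)
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_result", class(out))
  out
}
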