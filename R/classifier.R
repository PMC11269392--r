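#' Train the masked-feature neural network classifier
#'
#' Trains a single-hidden-layer neural network on binary CpG profiles with
#' random feature masking: at every epoch each training sample has a random
#' fraction of its CpG features (drawn uniformly from `mask_range`) set to the
#' missing encoding before the forward pass. Because sparse nanopore runs
#' observe anywhere from under 1% to over 80% of atlas CpGs, masking makes
#' the network natively robust to arbitrary missingness patterns at
#' prediction time — missing features at prediction use exactly the same
#' encoding as training-time masking.
#'
#' Missing values are encoded as a zero in the value channel plus a parallel
#' binary observed-indicator channel concatenated to the input, so the model
#' can distinguish "unmethylated" from "unobserved". Raw network outputs are
#' converted to probabilities by temperature scaling (the temperature fitted
#' on a held-out split by minimizing negative log-likelihood) followed by a
#' softmax, yielding a calibrated classification score.
#'
#' @param atlas A zero-variance-filtered `ref_atlas` with at least two
#'   classes and two samples per class.
#' @param hidden Hidden-layer width (ReLU units).
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param mask_range Length-2 numeric; per-sample mask rates are drawn
#'   uniformly from this interval. `c(0, 0)` disables masking and reduces to
#'   conventional supervised training.
#' @param val_fraction Fraction of samples per class held out for the
#'   convergence check and temperature fitting.
#' @param min_accuracy Held-out accuracy below which a convergence warning is
#'   raised.
#' @param seed Integer seed; fixes the split, masking, initialization and
#'   batch order, making training fully deterministic.
#'
#' @return An object of class `"masked_net"` with layer weights, the fixed
#'   class order, the class-to-family hierarchy, the fitted temperature, and
#'   training metadata.
#' @export
train_masked_net <- function(atlas, hidden = 256, epochs = 60, lr = 1e-3,
                             batch_size = 32, mask_range = c(0.3, 0.99),
                             val_fraction = 0.25, min_accuracy = 0.9,
                             seed = 1L) {
  stopifnot(inherits(atlas, "ref_atlas"))
  classes <- sort(unique(atlas$labels$class))
  if (length(classes) < 2) abort("atlas must contain at least two classes")
  if (min(table(atlas$labels$class)) < 2) abort("need at least two samples per class")
  if (length(mask_range) != 2 || mask_range[1] > mask_range[2] ||
      mask_range[1] < 0 || mask_range[2] > 1) {
    abort("mask_range must be an increasing interval within [0, 1]")
  }

  X <- atlas$matrix
  storage.mode(X) <- "double"
  y <- match(atlas$labels$class, classes)
  n <- nrow(X); d <- ncol(X); k <- length(classes)

  with_seed_(seed, {
    # stratified held-out split
    val_idx <- unlist(lapply(split(seq_len(n), y), function(ix) {
      n_val <- max(1L, floor(length(ix) * val_fraction))
      sample(ix, n_val)
    }), use.names = FALSE)
    tr_idx <- setdiff(seq_len(n), val_idx)

    par <- init_net(d, hidden, k)
    adam <- init_adam(par)
    Ytr <- onehot(y[tr_idx], k)

    for (ep in seq_len(epochs)) {
      rates <- runif(length(tr_idx), mask_range[1], mask_range[2])
      M <- matrix(rbinom(length(tr_idx) * d, 1L, rep(1 - rates, d)),
                  nrow = length(tr_idx), ncol = d)
      Xin <- cbind(X[tr_idx, , drop = FALSE] * M, M)
      ord <- sample(length(tr_idx))
      for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
        g <- net_grad(par, Xin[b, , drop = FALSE], Ytr[b, , drop = FALSE])
        if (!all(vapply(g, function(m) all(is.finite(m)), logical(1)))) {
          abort(sprintf("training failure: non-finite gradient at epoch %d", ep))
        }
        upd <- adam_step(adam, par, g, lr)
        par <- upd$par; adam <- upd$adam
      }
    }

    # convergence check on fully observed held-out samples
    logits_val <- net_logits(par, encode_input(X[val_idx, , drop = FALSE]))
    val_acc <- mean(max.col(logits_val, ties.method = "first") == y[val_idx])
    if (val_acc < min_accuracy) {
      warn(sprintf("classifier did not reach target held-out accuracy (%.3f < %.3f)",
                   val_acc, min_accuracy))
    }

    # temperature fitted on held-out samples under representative mask rates
    temp <- fit_temperature(par, X[val_idx, , drop = FALSE], y[val_idx],
                            mask_range, k)

    structure(
      list(par = par, classes = classes, hierarchy = atlas$hierarchy,
           temperature = temp, input_dim = d,
           config = list(hidden = hidden, epochs = epochs, lr = lr,
                         batch_size = batch_size, mask_range = mask_range,
                         val_fraction = val_fraction, seed = seed),
           metrics = list(val_accuracy = val_acc, n_train = length(tr_idx),
                          n_val = length(val_idx))),
      class = "masked_net"
    )
  })
}

init_net <- function(d, h, k) {
  list(
    W1 = matrix(rnorm(2 * d * h, 0, sqrt(2 / (2 * d))), nrow = 2 * d, ncol = h),
    b1 = rep(0, h),
    W2 = matrix(rnorm(h * k, 0, sqrt(2 / h)), nrow = h, ncol = k),
    b2 = rep(0, k)
  )
}

onehot <- function(y, k) {
  Y <- matrix(0, length(y), k)
  Y[cbind(seq_along(y), y)] <- 1
  Y
}

encode_input <- function(X) {
  # value channel (missing -> 0) + observed-indicator channel
  M <- 1 - is.na(X)
  X[is.na(X)] <- 0
  cbind(X * M, M)
}

net_logits <- function(par, Xin) {
  H <- pmax(sweep(Xin %*% par$W1, 2, par$b1, "+"), 0)
  sweep(H %*% par$W2, 2, par$b2, "+")
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

net_grad <- function(par, Xin, Y) {
  nb <- nrow(Xin)
  Z1 <- sweep(Xin %*% par$W1, 2, par$b1, "+")
  H <- pmax(Z1, 0)
  P <- softmax_rows(sweep(H %*% par$W2, 2, par$b2, "+"))
  dZ2 <- (P - Y) / nb
  dH <- dZ2 %*% t(par$W2)
  dZ1 <- dH * (Z1 > 0)
  list(
    W1 = crossprod(Xin, dZ1), b1 = colSums(dZ1),
    W2 = crossprod(H, dZ2), b2 = colSums(dZ2)
  )
}

init_adam <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(adam, par, grad, lr) {
  adam$t <- adam$t + 1L
  for (nm in names(par)) {
    adam$m[[nm]] <- adam$beta1 * adam$m[[nm]] + (1 - adam$beta1) * grad[[nm]]
    adam$v[[nm]] <- adam$beta2 * adam$v[[nm]] + (1 - adam$beta2) * grad[[nm]]^2
    mhat <- adam$m[[nm]] / (1 - adam$beta1^adam$t)
    vhat <- adam$v[[nm]] / (1 - adam$beta2^adam$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + adam$eps)
  }
  list(par = par, adam = adam)
}

fit_temperature <- function(par, Xval, yval, mask_range, k) {
  d <- ncol(Xval)
  rates <- seq(mask_range[1], mask_range[2], length.out = 3)
  logits <- NULL; labels <- NULL
  for (r in rates) {
    M <- matrix(rbinom(length(Xval), 1L, 1 - r), nrow = nrow(Xval))
    logits <- rbind(logits, net_logits(par, cbind(Xval * M, M)))
    labels <- c(labels, yval)
  }
  nll <- function(log_tau) {
    P <- softmax_rows(logits / exp(log_tau))
    -mean(log(pmax(P[cbind(seq_along(labels), labels)], 1e-12)))
  }
  exp(optimize(nll, c(log(0.05), log(50)))$minimum)
}

#' @export
print.masked_net <- function(x, ...) {
  cat(sprintf(
    "<masked_net> %d CpG features, %d classes, hidden=%d, temperature=%.2f, held-out accuracy=%.3f\n",
    x$input_dim, length(x$classes), x$config$hidden, x$temperature,
    x$metrics$val_accuracy
  ))
  invisible(x)
}

#' Per-class softmax scores for one or more cases
#'
#' Missing features (`NA`) receive the same zero-plus-indicator encoding used
#' by training-time masking. Logits are divided by the fitted temperature and
#' passed through a softmax, so scores are calibrated probabilities summing
#' to one over classes.
#'
#' @param object A `masked_net` model.
#' @param newdata A `feature_vector`, a numeric vector with `NA` for missing
#'   features, or a matrix of such rows (one case per row).
#' @param ... Unused.
#' @return A tibble with columns `class` and `score` (plus `case` when
#'   `newdata` is a matrix with more than one row).
#' @export
predict.masked_net <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_vector")) newdata <- newdata$values
  single <- is.null(dim(newdata))
  X <- if (single) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(X) != object$input_dim) {
    abort(sprintf("dimension mismatch: model expects %d features, got %d",
                  object$input_dim, ncol(X)))
  }
  P <- softmax_rows(net_logits(object$par, encode_input(X)) / object$temperature)
  colnames(P) <- object$classes
  if (single) {
    tibble(class = object$classes, score = as.numeric(P[1, ]))
  } else {
    ids <- rownames(X) %||% sprintf("case_%d", seq_len(nrow(X)))
    tidyr::pivot_longer(
      dplyr::bind_cols(tibble(case = ids), as_tibble(P)),
      -"case", names_to = "class", values_to = "score"
    )
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate class scores to methylation class family scores
#'
#' A family's score is the exact sum of its member class scores, so the family
#' distribution conserves probability mass and a family score is always at
#' least the score of its highest-scoring member class.
#'
#' @param scores Tibble with columns `class` and `score` (optionally `case`).
#' @param hierarchy Tibble (`class`, `family`) covering every scored class.
#' @return Tibble with columns `family` and `score` (and `case` if present),
#'   sorted by family.
#' @examples
#' scores <- tibble::tibble(class = c("A1", "A2", "B1", "B2"),
#'                          score = c(0.3, 0.2, 0.4, 0.1))
#' hier <- tibble::tibble(class = c("A1", "A2", "B1", "B2"),
#'                        family = c("A", "A", "B", "B"))
#' aggregate_families(scores, hier)
#' @export
aggregate_families <- function(scores, hierarchy) {
  missing_cls <- setdiff(unique(scores$class), hierarchy$class)
  if (length(missing_cls) > 0) {
    abort(paste0("class missing from hierarchy: ", paste(missing_cls, collapse = ", ")))
  }
  joined <- left_join(scores, hierarchy, by = "class")
  grp <- if ("case" %in% names(scores)) c("case", "family") else "family"
  joined %>%
    group_by(dplyr::across(dplyr::all_of(grp))) %>%
    summarise(score = sum(.data$score), .groups = "drop") %>%
    arrange(dplyr::across(dplyr::all_of(grp)))
}

#' Top-scoring call from a score distribution
#'
#' Returns the label with the maximal score. Exact ties are broken by
#' lexicographic label order and flagged, never silently resolved.
#'
#' @param scores Tibble with a label column (`class` or `family`) and a
#'   `score` column.
#' @return One-row tibble (`label`, `score`, `tie`).
#' @export
top_call <- function(scores) {
  if (nrow(scores) == 0) abort("empty score table")
  label_col <- intersect(c("class", "family"), names(scores))[1]
  if (is.na(label_col)) abort("scores must have a 'class' or 'family' column")
  best <- max(scores$score)
  hits <- sort(scores[[label_col]][scores$score >= best - 1e-12])
  tibble(label = hits[1], score = best, tie = length(hits) > 1)
}

#' @export
tidy.masked_net <- function(x, ...) {
  left_join(tibble(class = x$classes), x$hierarchy, by = "class")
}

#' @export
glance.masked_net <- function(x, ...) {
  tibble(
    n_classes = length(x$classes),
    n_features = x$input_dim,
    hidden = x$config$hidden,
    epochs = x$config$epochs,
    mask_lo = x$config$mask_range[1],
    mask_hi = x$config$mask_range[2],
    temperature = x$temperature,
    val_accuracy = x$metrics$val_accuracy,
    n_train = x$metrics$n_train,
    n_val = x$metrics$n_val
  )
}
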