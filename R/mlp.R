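# Three-layer backpropagation neural network: input layer, logistic
# hidden layer(s), single logistic output trained by full-batch Adam on
# cross-entropy, with early stopping monitored on a held-out validation
# split. Features are z-scored with training-set statistics inside the
# fit, so validation and test data never leak into standardization.

#' Fit a backpropagation neural-network classifier
#'
#' A multilayer perceptron with logistic activations throughout and a
#' single probabilistic output, trained by full-batch gradient descent
#' (Adam) on binary cross-entropy. When a validation set is supplied,
#' training keeps the weights achieving the lowest validation loss and
#' stops after `patience` epochs without improvement -- the role the 15%
#' validation partition plays in the repeated-split design.
#'
#' @param x numeric matrix or data frame of predictors (rows = patients).
#' @param y binary outcome (any coding accepted by the package's label
#'   handling; positive class = expansion).
#' @param hidden integer vector of hidden-layer widths; the default
#'   `10` gives the classic input-hidden-output three-layer network, and
#'   e.g. `c(10, 10)` gives two hidden layers.
#' @param epochs maximum training epochs (default 500).
#' @param lr Adam learning rate (default 0.05).
#' @param patience early-stopping patience in epochs (default 20);
#'   ignored without a validation set.
#' @param validation optional list `list(x =, y =)` held-out validation
#'   data on the raw feature scale.
#' @param seed integer seed for weight initialisation (reproducible fits).
#' @return Object of class `mlp_net`: weight matrices `W` and biases `b`
#'   per layer, the training-set standardization (`center`, `scale`),
#'   `best_epoch`, and the training/validation loss `history`.
#' @examples
#' x <- matrix(rnorm(120), 60, 2); y <- as.integer(x[, 1] + x[, 2] > 0)
#' fit <- mlp_net(x, y, seed = 1)
#' head(predict(fit, x))
#' @export
mlp_net <- function(x, y, hidden = 10L, epochs = 500L, lr = 0.05,
                    patience = 20L, validation = NULL, seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as_binary_label(y)
  if (nrow(x) != length(y)) stop("`x` rows must match `y` length", call. = FALSE)
  bad <- colnames(x)[!apply(is.finite(x), 2, all)]
  if (ncol(x) > 0 && any(!is.finite(x)))
    stop(sprintf("non-finite feature values in column(s): %s",
                 paste(if (length(bad)) bad else "<unnamed>", collapse = ", ")),
         call. = FALSE)

  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1    # constant columns contribute nothing
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  has_val <- !is.null(validation)
  if (has_val) {
    xv <- sweep(sweep(as.matrix(validation$x), 2, ctr), 2, scl, "/")
    yv <- as_binary_label(validation$y)
  }

  sizes <- c(ncol(x), as.integer(hidden), 1L)
  L <- length(sizes) - 1L
  with_seed(seed, {
    W <- lapply(seq_len(L), function(l)
      matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0, 1 / sqrt(max(1, sizes[l]))),
             sizes[l], sizes[l + 1]))
    b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))

    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(v) v * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    sigm <- function(z) 1 / (1 + exp(-z))
    fwd <- function(X, W, b) {
      A <- vector("list", L + 1L); A[[1]] <- X
      for (l in seq_len(L))
        A[[l + 1]] <- sigm(sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+"))
      A
    }
    bce <- function(p, y) {
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -mean(y * log(p) + (1 - y) * log(1 - p))
    }

    best <- list(W = W, b = b, loss = Inf, epoch = 0L)
    hist_tr <- hist_va <- numeric(0)
    stall <- 0L
    n <- nrow(xs)
    for (ep in seq_len(epochs)) {
      A <- fwd(xs, W, b)
      p <- A[[L + 1]][, 1]
      # delta for logistic output + cross-entropy
      D <- matrix((p - y) / n, n, 1)
      for (l in rev(seq_len(L))) {
        gW <- crossprod(A[[l]], D)
        gb <- colSums(D)
        if (l > 1) {
          H <- A[[l]]
          D <- (D %*% t(W[[l]])) * H * (1 - H)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhW <- mW[[l]] / (1 - beta1^ep); vhW <- vW[[l]] / (1 - beta2^ep)
        mhb <- mb[[l]] / (1 - beta1^ep); vhb <- vb[[l]] / (1 - beta2^ep)
        W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
        b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
      }
      hist_tr[ep] <- bce(p, y)
      if (has_val) {
        pv <- fwd(xv, W, b)[[L + 1]][, 1]
        hist_va[ep] <- bce(pv, yv)
        if (hist_va[ep] < best$loss - 1e-9) {
          best <- list(W = W, b = b, loss = hist_va[ep], epoch = ep)
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= patience) break
        }
      } else {
        best <- list(W = W, b = b, loss = hist_tr[ep], epoch = ep)
      }
    }

    structure(list(W = best$W, b = best$b, center = ctr, scale = scl,
                   sizes = sizes, best_epoch = best$epoch,
                   val_loss = if (has_val) best$loss else NA_real_,
                   history = list(train = hist_tr, validation = hist_va),
                   feature_names = colnames(x)),
              class = "mlp_net")
  })
}

#' Predict expansion scores from a fitted network
#'
#' @param object a fitted [mlp_net()].
#' @param newdata matrix or data frame on the raw feature scale.
#' @param ... unused.
#' @return Numeric vector of scores in (0, 1).
#' @export
predict.mlp_net <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  A <- X
  L <- length(object$W)
  for (l in seq_len(L))
    A <- 1 / (1 + exp(-sweep(A %*% object$W[[l]], 2, object$b[[l]], "+")))
  A[, 1]
}

#' @export
print.mlp_net <- function(x, ...) {
  cat(sprintf("Backpropagation neural network: %s units, logistic activations\n",
              paste(x$sizes, collapse = "-")))
  cat(sprintf("  best epoch %d%s\n", x$best_epoch,
              if (is.na(x$val_loss)) "" else
                sprintf(", validation cross-entropy %.4f", x$val_loss)))
  invisible(x)
}

#' @export
summary.mlp_net <- function(object, ...) {
  cat(sprintf("Layer sizes: %s (%d weights)\n",
              paste(object$sizes, collapse = " -> "),
              sum(vapply(object$W, length, integer(1))) +
                sum(vapply(object$b, length, integer(1)))))
  cat(sprintf("Trained %d epoch(s); kept epoch %d\n",
              length(object$history$train), object$best_epoch))
  invisible(object)
}

#' @export
coef.mlp_net <- function(object, ...) {
  stats::setNames(list(weights = object$W, biases = object$b), c("weights", "biases"))
}

#' @export
plot.mlp_net <- function(x, ...) {
  h <- x$history
  graphics::plot(h$train, type = "l", xlab = "epoch", ylab = "cross-entropy",
                 ylim = range(c(h$train, h$validation), finite = TRUE), ...)
  if (length(h$validation)) {
    graphics::lines(h$validation, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  }
  graphics::abline(v = x$best_epoch, col = "grey60", lty = 3)
  invisible(x)
}
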