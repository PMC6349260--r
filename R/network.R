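#' Specify a retrieval network
#'
#' Describes one of the three bidirectional LSTM retrieval networks: all
#' share three bidirectional recurrent layers of 30 units and a 29-step,
#' 7-band input; they differ in the head. The `physical` head emits one
#' linear channel per state variable per step (squared-error loss on
#' z-scored targets); the `yield` head emits one channel whose 29 per-step
#' outputs are averaged into a single yield (squared-error loss); the
#' `phenology` head emits one channel per merged stage with a per-step
#' softmax and cross-entropy loss against stage fractions.
#'
#' @param head `"physical"`, `"yield"` or `"phenology"`.
#' @param n_out output channels (state variables or merged stages; forced
#'   to 1 for the yield head).
#' @param layers,units recurrent depth and width.
#' @param learning_rate,batch_size Adam step size and minibatch size.
#' @param patience early-stopping patience in epochs.
#' @param max_epochs epoch cap.
#' @return a list of class `simcal_netspec`.
#' @export
network_spec <- function(head = c("physical", "yield", "phenology"),
                         n_out = NULL, layers = 3L, units = 30L,
                         learning_rate = 3e-3, batch_size = 32L,
                         patience = 30L, max_epochs = 300L) {
  head <- match.arg(head)
  if (layers < 1L || units < 1L) stop("layer and unit counts must be positive",
                                      call. = FALSE)
  if (patience < 1L) stop("patience must be at least 1", call. = FALSE)
  if (is.null(n_out)) {
    n_out <- switch(head, physical = length(state_var_names()),
                    yield = 1L, phenology = 6L)
  }
  if (head == "yield") n_out <- 1L
  structure(list(head = head, n_out = as.integer(n_out),
                 layers = as.integer(layers), units = as.integer(units),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 n_in = 7L, seq_len = 29L),
            class = "simcal_netspec")
}

head_code <- function(head) {
  match(head, c("physical", "yield", "phenology")) - 1L
}

# initialise the flat parameter vector: uniform fan-in scaled weights,
# all trainable biases set to 1
init_params <- function(spec, seed) {
  set.seed(seed)
  n <- blstm_n_params(spec$n_in, spec$units, spec$layers, spec$n_out)
  H <- spec$units
  p <- numeric(n)
  off <- 0L
  for (l in seq_len(spec$layers)) {
    D <- if (l == 1L) spec$n_in else 2L * H
    for (d in 1:2) {
      nwx <- 4L * H * D; nwh <- 4L * H * H
      p[off + seq_len(nwx)] <- stats::runif(nwx, -1, 1) / sqrt(D)
      off <- off + nwx
      p[off + seq_len(nwh)] <- stats::runif(nwh, -1, 1) / sqrt(H)
      off <- off + nwh
      p[off + seq_len(4L * H)] <- 1
      off <- off + 4L * H
    }
  }
  nwo <- spec$n_out * 2L * H
  p[off + seq_len(nwo)] <- stats::runif(nwo, -1, 1) / sqrt(2 * H)
  off <- off + nwo
  p[off + seq_len(spec$n_out)] <- 1
  p
}

#' Fit a per-variable target scaler on training data
#'
#' @param x a matrix or 3-d array whose last margin (columns of a matrix,
#'   third margin of an array) indexes variables.
#' @return list of class `simcal_scaler` with per-variable `mean` and `sd`
#'   (zero-variance variables get sd 1).
#' @export
fit_scaler <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  nv <- dim(x)[length(dim(x))]
  flat <- matrix(aperm_to_last(x), ncol = nv)
  mu <- colMeans(flat)
  sd_ <- apply(flat, 2L, stats::sd)
  sd_[!is.finite(sd_) | sd_ <= 0] <- 1
  structure(list(mean = mu, sd = sd_), class = "simcal_scaler")
}

aperm_to_last <- function(x) {
  if (length(dim(x)) == 3L) {
    matrix(x, ncol = dim(x)[3L])
  } else x
}

#' Apply (or invert) a scaler
#'
#' @param scaler a `simcal_scaler`.
#' @param x data shaped as in [fit_scaler()].
#' @param invert if `TRUE`, undo the transform.
#' @return `x` transformed, same shape.
#' @export
apply_scaler <- function(scaler, x, invert = FALSE) {
  d <- dim(x)
  nv <- length(scaler$mean)
  if (is.null(d)) {
    return(if (invert) x * scaler$sd + scaler$mean
           else (x - scaler$mean) / scaler$sd)
  }
  flat <- matrix(x, ncol = nv)
  out <- if (invert) sweep(sweep(flat, 2L, scaler$sd, "*"), 2L, scaler$mean, "+")
  else sweep(sweep(flat, 2L, scaler$mean, "-"), 2L, scaler$sd, "/")
  dim(out) <- d
  out
}

# reorder an (n_seq x T x F) array into the (n_seq x F x T) cube layout the
# C++ core expects
to_cube <- function(x) aperm(x, c(1L, 3L, 2L))

net_loss <- function(params, spec, x_cube, y) {
  blstm_loss_grad(params, x_cube, y, head_code(spec$head), spec$layers,
                  spec$units, spec$n_out, FALSE)$loss
}

#' Train a retrieval network with early stopping
#'
#' Minibatch Adam on the head loss; training stops when the validation loss
#' has not improved for `patience` consecutive epochs (or at `max_epochs`),
#' and the parameters of the best validation epoch are returned.
#' Reproducible given the seed.
#'
#' @param spec a `simcal_netspec`.
#' @param x_train,x_val input arrays `(n_seq, 29, 7)` (already scaled as
#'   desired).
#' @param y_train,y_val targets: arrays `(n_seq, 29, n_out)` for the
#'   physical and phenology heads, numeric vectors for the yield head.
#' @param seed integer seed (initialisation and batch order).
#' @param verbose print the epoch trace.
#' @return a list of class `simcal_network` with `params`, `spec`,
#'   `history` (per-epoch train/validation loss), `best_epoch`,
#'   `stopped_epoch`.
#' @export
train_network <- function(spec, x_train, y_train, x_val, y_val, seed = 1L,
                          verbose = FALSE) {
  xc_train <- to_cube(x_train)
  xc_val <- to_cube(x_val)
  yc_train <- if (spec$head == "yield") y_train else to_cube(y_train)
  yc_val <- if (spec$head == "yield") y_val else to_cube(y_val)
  n <- dim(x_train)[1L]

  params <- init_params(spec, seed)
  m <- numeric(length(params)); v <- numeric(length(params))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- spec$learning_rate
  step <- 0L

  set.seed(seed + 1L)
  best_val <- Inf; best_params <- params; best_epoch <- 0L
  hist_train <- numeric(0); hist_val <- numeric(0)
  epoch <- 0L
  while (epoch < spec$max_epochs) {
    epoch <- epoch + 1L
    ord <- sample.int(n)
    starts <- seq(1L, n, by = spec$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + spec$batch_size - 1L, n)]
      xb <- xc_train[idx, , , drop = FALSE]
      yb <- if (spec$head == "yield") yc_train[idx]
      else yc_train[idx, , , drop = FALSE]
      out <- blstm_loss_grad(params, xb, yb, head_code(spec$head),
                             spec$layers, spec$units, spec$n_out, TRUE)
      g <- out$grad
      step <- step + 1L
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g * g
      mhat <- m / (1 - b1^step)
      vhat <- v / (1 - b2^step)
      params <- params - lr * mhat / (sqrt(vhat) + eps)
      ep_loss <- ep_loss + out$loss * length(idx)
    }
    val_loss <- net_loss(params, spec, xc_val, yc_val)
    hist_train <- c(hist_train, ep_loss / n)
    hist_val <- c(hist_val, val_loss)
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss; best_params <- params; best_epoch <- epoch
    }
    if (verbose) {
      message(sprintf("epoch %3d train %.5f val %.5f", epoch,
                      ep_loss / n, val_loss))
    }
    if (epoch - best_epoch >= spec$patience) break
  }

  structure(list(params = best_params, spec = spec,
                 history = data.frame(epoch = seq_along(hist_train),
                                      train_loss = hist_train,
                                      val_loss = hist_val),
                 best_epoch = best_epoch, stopped_epoch = epoch),
            class = "simcal_network")
}

#' Predict with a trained retrieval network
#'
#' @param object a `simcal_network`.
#' @param x input array `(n_seq, 29, 7)` scaled as in training.
#' @param ... unused.
#' @return the head-specific output: `(n_seq, 29, n_out)` array for the
#'   physical head (in scaled target units), numeric vector for the yield
#'   head, `(n_seq, 29, n_stages)` row-stochastic array for the phenology
#'   head.
#' @export
predict.simcal_network <- function(object, x, ...) {
  spec <- object$spec
  if (length(dim(x)) != 3L || dim(x)[2L] != spec$seq_len ||
      dim(x)[3L] != spec$n_in) {
    stop("input must be an (n, ", spec$seq_len, ", ", spec$n_in, ") array",
         call. = FALSE)
  }
  out <- blstm_forward(object$params, to_cube(x), head_code(spec$head),
                       spec$layers, spec$units, spec$n_out)$pred
  if (spec$head == "yield") return(as.numeric(out))
  aperm(out, c(1L, 3L, 2L))  # back to (n, T, n_out)
}

#' Serialise a network topology description to JSON
#'
#' Writes the layer structure (sizes, directions, head type) as a JSON
#' object; weights are saved separately with [saveRDS()] by the caller if
#' needed.
#'
#' @param spec a `simcal_netspec`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(spec, path) {
  desc <- list(
    input = list(width = spec$n_in, steps = spec$seq_len),
    layers = lapply(seq_len(spec$layers), function(l)
      list(type = "blstm", units = spec$units, bidirectional = TRUE,
           bias = 1)),
    head = list(type = spec$head, channels = spec$n_out,
                activation = switch(spec$head, physical = "identity",
                                    yield = "identity-mean",
                                    phenology = "softmax"))
  )
  jsonlite::write_json(desc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
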