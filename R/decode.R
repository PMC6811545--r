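#' Extract per-neuron spike trains from a raster
#'
#' @param raster a `spike_raster` (or tidy data.frame with `neuron`,
#'   `t_ms`)
#' @param neurons neuron ids
#' @param window optional `c(start, end)` (ms) to restrict spikes
#' @return a named list of spike-time vectors, one per requested neuron
#' @export
neuron_trains <- function(raster, neurons, window = NULL) {
  df <- if (inherits(raster, "spike_raster")) raster$spikes else raster
  if (!is.null(window)) {
    df <- df[df$t_ms >= window[1] & df$t_ms < window[2], , drop = FALSE]
  }
  out <- lapply(neurons, function(id) df$t_ms[df$neuron == id])
  names(out) <- as.character(neurons)
  out
}

#' Binned spike-count feature matrix for population decoding
#'
#' One row per trial; columns are the concatenated per-neuron, per-bin
#' spike counts of the requested ensemble over the analysis window.
#'
#' @param rasters list of `spike_raster` objects (the trials)
#' @param ensemble neuron ids to include (non-empty)
#' @param bin_ms bin width (ms); default 10
#' @param window `c(start, end)` (ms); default the full raster duration
#' @return numeric matrix, trials x (length(ensemble) * n_bins)
#' @export
featurize <- function(rasters, ensemble, bin_ms = 10, window = NULL) {
  if (!length(ensemble)) stop("ensemble must be non-empty", call. = FALSE)
  if (is.null(window)) window <- c(0, rasters[[1]]$duration)
  n_bins <- as.integer(ceiling((window[2] - window[1]) / bin_ms))
  breaks <- window[1] + seq(0, n_bins) * bin_ms
  t(vapply(rasters, function(r) {
    df <- if (inherits(r, "spike_raster")) r$spikes else r
    unlist(lapply(ensemble, function(id) {
      ts <- df$t_ms[df$neuron == id & df$t_ms >= window[1] &
                      df$t_ms < window[2]]
      if (!length(ts)) return(numeric(n_bins))
      tabulate(pmin(as.integer(floor((ts - window[1]) / bin_ms)) + 1L,
                    n_bins), nbins = n_bins)
    }))
  }, numeric(length(ensemble) * n_bins)))
}

# Solve (alpha I + V diag(d) V') x = y for each column of y using the
# Woodbury identity on the low-rank part (V: p x r).  Exact; avoids ever
# forming the p x p covariance.
shrinkage_solve <- function(V, d, alpha, y) {
  y <- as.matrix(y)
  Vy <- crossprod(V, y)
  y / alpha - V %*% (Vy * (d / (alpha * (alpha + d))))
}

#' Train a regularised linear population decoder
#'
#' Fisher linear discriminant with a shrinkage-regularised pooled
#' covariance.  With `method = "shrinkage"` (default) the covariance is
#' `(1 - lambda) S + lambda cbar I`, where `cbar` is the mean diagonal of
#' the pooled covariance `S` (scale-preserving: at `lambda = 1` the rule
#' reduces to nearest class mean).  `method = "additive"` uses
#' `S + lambda I` instead.  The high-dimensional solve uses the Woodbury
#' identity on the (rank <= trials) pooled scatter, so feature counts far
#' exceeding trial counts are handled exactly.
#'
#' @param X feature matrix (trials x features), e.g. from [featurize()]
#' @param y binary labels (two distinct values; factor, character or
#'   numeric)
#' @param lambda regularisation weight in `[0, 1]`; default 0.05
#' @param method `"shrinkage"` or `"additive"`
#' @return a list of class `linear_decoder`: `w`, `threshold`, `classes`,
#'   plus a `predict` method
#' @export
train_linear_decoder <- function(X, y, lambda = 0.05,
                                 method = c("shrinkage", "additive")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  cls <- sort(unique(as.character(y)))
  if (length(cls) != 2) {
    stop("need exactly two classes in y; got ", length(cls), call. = FALSE)
  }
  y <- as.character(y)
  i0 <- y == cls[1]; i1 <- y == cls[2]
  mu0 <- colMeans(X[i0, , drop = FALSE])
  mu1 <- colMeans(X[i1, , drop = FALSE])
  Xc <- rbind(sweep(X[i0, , drop = FALSE], 2, mu0),
              sweep(X[i1, , drop = FALSE], 2, mu1))
  dof <- max(nrow(X) - 2, 1)
  sv <- svd(Xc, nu = 0)
  keep <- sv$d > max(sv$d[1], 0) * 1e-12
  V <- sv$v[, keep, drop = FALSE]
  ssq <- sv$d[keep]^2 / dof
  cbar <- sum(Xc^2) / (dof * ncol(X))
  if (method == "shrinkage") {
    alpha <- lambda * max(cbar, .Machine$double.eps)
    d <- (1 - lambda) * ssq
  } else {
    alpha <- lambda
    d <- ssq
  }
  w <- drop(shrinkage_solve(V, d, alpha, mu1 - mu0))
  structure(
    list(w = w, threshold = sum(w * (mu0 + mu1)) / 2, classes = cls,
         lambda = lambda, method = method),
    class = "linear_decoder"
  )
}

#' @export
predict.linear_decoder <- function(object, newdata, ...) {
  s <- as.matrix(newdata) %*% object$w
  object$classes[ifelse(drop(s) > object$threshold, 2, 1)]
}

#' Leave-one-out cross-validated decoding error
#'
#' One fold per trial: the decoder is trained on all remaining trials and
#' asked to predict the held-out trial's label.  Optionally computes a
#' label-permutation null distribution of the same LOOCV error for the
#' chance-level comparison.
#'
#' @inheritParams train_linear_decoder
#' @param n_perm number of label permutations for the null (0 to skip)
#' @param seed integer seed for the permutations
#' @return a list of class `decode_result`: `error` in `[0, 1]`,
#'   `predictions`, `null_errors` (length `n_perm`), `n_folds`
#' @export
loo_cv <- function(X, y, lambda = 0.05, method = c("shrinkage", "additive"),
                   n_perm = 0, seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- as.character(y)
  if (min(table(y)) < 2) stop("need >= 2 trials per class", call. = FALSE)
  run_loo <- function(labels) {
    preds <- character(nrow(X))
    for (i in seq_len(nrow(X))) {
      dec <- train_linear_decoder(X[-i, , drop = FALSE], labels[-i],
                                  lambda, method)
      preds[i] <- predict(dec, X[i, , drop = FALSE])
    }
    preds
  }
  preds <- run_loo(y)
  nulls <- if (n_perm > 0) {
    with_seed(seed, vapply(seq_len(n_perm), function(p) {
      yp <- sample(y)
      mean(run_loo(yp) != yp)
    }, numeric(1)))
  } else numeric(0)
  structure(
    list(error = mean(preds != y), predictions = preds,
         null_errors = nulls, n_folds = nrow(X)),
    class = "decode_result"
  )
}

#' Decoding error as a function of ensemble size
#'
#' For each genotype and each requested ensemble size, repeatedly draws
#' random ensembles of excitatory neurons, decodes regular versus oddball
#' trials by leave-one-out cross-validation, and averages the error across
#' draws, network seeds and oddball positions (decoded per position).
#'
#' @param experiment an [run_experiment()] result containing regular and
#'   oddball trials
#' @param sizes ensemble sizes (each <= the excitatory population size)
#' @param permutations random ensemble draws per size
#' @param bin_ms feature bin width (ms)
#' @param lambda decoder regularisation
#' @param seed integer seed for the ensemble draws
#' @return data.frame: `genotype`, `size`, `mean_error`, `sd_error`, `n`
#' @export
ensemble_curve <- function(experiment, sizes = c(10, 20, 50),
                           permutations = 10, bin_ms = 10, lambda = 0.05,
                           seed = 1L) {
  stopifnot(inherits(experiment, "l4_experiment"))
  runs <- experiment$runs
  meta <- data.frame(
    genotype = vapply(runs, `[[`, character(1), "genotype"),
    net_seed = vapply(runs, `[[`, numeric(1), "net_seed"),
    frequency = vapply(runs, `[[`, numeric(1), "frequency"),
    oddball = vapply(runs, function(r) as.integer(r$oddball %||% NA),
                     integer(1)),
    stringsAsFactors = FALSE
  )
  n_ex <- runs[[1]]$raster$n_ex
  if (any(sizes > n_ex)) {
    stop("ensemble size exceeds the excitatory population (", n_ex, ")",
         call. = FALSE)
  }
  out <- list()
  for (gl in unique(meta$genotype)) {
    errs_by_size <- lapply(sizes, function(s) numeric(0))
    names(errs_by_size) <- as.character(sizes)
    for (ns in unique(meta$net_seed[meta$genotype == gl])) {
      for (f in unique(meta$frequency)) {
        sel <- meta$genotype == gl & meta$net_seed == ns & meta$frequency == f
        reg_idx <- which(sel & is.na(meta$oddball))
        odd_pos <- unique(stats::na.omit(meta$oddball[sel]))
        for (pos in odd_pos) {
          odd_idx <- which(sel & !is.na(meta$oddball) & meta$oddball == pos)
          rasters <- lapply(c(reg_idx, odd_idx), function(i) runs[[i]]$raster)
          labels <- rep(c("regular", "oddball"),
                        c(length(reg_idx), length(odd_idx)))
          for (si in seq_along(sizes)) {
            s <- sizes[si]
            for (pm in seq_len(permutations)) {
              ens <- with_seed(
                child_seed(seed, si * 10000 + pm * 100 + pos), {
                  sample(n_ex, s)
                })
              X <- featurize(rasters, ens, bin_ms)
              res <- loo_cv(X, labels, lambda)
              errs_by_size[[as.character(s)]] <-
                c(errs_by_size[[as.character(s)]], res$error)
            }
          }
        }
      }
    }
    out[[gl]] <- data.frame(
      genotype = gl, size = sizes,
      mean_error = vapply(errs_by_size, mean, numeric(1)),
      sd_error = vapply(errs_by_size, stats::sd, numeric(1)),
      n = vapply(errs_by_size, length, numeric(1))
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Single-cell oddball representation summaries
#'
#' For each neuron, compares its responses on regular versus oddball
#' trials: change in per-trial spike count, change in mean first-spike
#' time, and the mean pairwise van Rossum distance between regular and
#' oddball spike trains.
#'
#' @param rasters_regular,rasters_oddball lists of `spike_raster` objects
#'   (matched trial counts not required; all cross pairs are used for the
#'   dissimilarity)
#' @param neurons neuron ids to summarise; default all excitatory neurons
#' @param window analysis window `c(start, end)` (ms); default full trial
#' @param tau van Rossum decay constant (ms)
#' @return data.frame: `neuron`, `delta_rate` (spikes/trial),
#'   `delta_first_ms`, `dissimilarity`
#' @export
oddball_single_cell <- function(rasters_regular, rasters_oddball,
                                neurons = NULL, window = NULL, tau = 50) {
  r1 <- rasters_regular[[1]]
  neurons <- neurons %||% seq_len(r1$n_ex)
  window <- window %||% c(0, r1$duration)
  rows <- lapply(neurons, function(id) {
    tr_reg <- lapply(rasters_regular, function(r)
      neuron_trains(r, id, window)[[1]])
    tr_odd <- lapply(rasters_oddball, function(r)
      neuron_trains(r, id, window)[[1]])
    cnt_reg <- vapply(tr_reg, length, integer(1))
    cnt_odd <- vapply(tr_odd, length, integer(1))
    first <- function(tl) {
      f <- unlist(lapply(tl, function(ts) if (length(ts)) min(ts) else NA))
      if (all(is.na(f))) NA_real_ else mean(f, na.rm = TRUE)
    }
    dists <- outer(seq_along(tr_reg), seq_along(tr_odd),
                   Vectorize(function(i, j)
                     van_rossum(tr_reg[[i]], tr_odd[[j]], tau)))
    data.frame(
      neuron = id,
      delta_rate = mean(cnt_odd) - mean(cnt_reg),
      delta_first_ms = first(tr_odd) - first(tr_reg),
      dissimilarity = mean(dists)
    )
  })
  do.call(rbind, rows)
}
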