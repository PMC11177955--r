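#' Construct a set of ROI signals
#'
#' @param values numeric matrix, one row per ROI, one column per time point
#' @param roi_labels character vector of row labels
#' @param tr_seconds sampling interval in seconds (fMRI repetition time)
#' @return an object of class `signal_set`
#' @export
signal_set <- function(values, roi_labels = rownames(values), tr_seconds = 2.5) {
  values <- as.matrix(values)
  if (is.null(roi_labels)) stop("roi_labels required", call. = FALSE)
  if (anyDuplicated(roi_labels)) stop("duplicate ROI labels", call. = FALSE)
  if (length(roi_labels) != nrow(values)) stop("label/row mismatch", call. = FALSE)
  if (ncol(values) < 2L) stop("need at least 2 time points", call. = FALSE)
  if (anyNA(values)) stop("missing values in signals", call. = FALSE)
  rownames(values) <- roi_labels
  structure(list(values = values, roi_labels = roi_labels,
                 tr_seconds = tr_seconds),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf("<signal_set> %d ROIs x %d time points, TR = %gs\n",
              nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}

# analytic signal of each row via FFT (zero negative frequencies)
analytic_signal <- function(x) {
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  X <- t(stats::mvfft(t(x)))
  z <- t(stats::mvfft(t(X * rep(h, each = nrow(x))), inverse = TRUE)) / n
  z
}

#' Instantaneous phases of ROI signals
#'
#' Each row is demeaned and its analytic signal computed (Hilbert transform
#' via FFT); the instantaneous phase is the argument of the analytic signal.
#'
#' @param s a `signal_set`
#' @return numeric matrix (ROI x time) of phases in (-pi, pi]
#' @export
instantaneous_phase <- function(s) {
  if (!inherits(s, "signal_set")) stop("expected a `signal_set`", call. = FALSE)
  x <- s$values - rowMeans(s$values)
  flat <- apply(x, 1L, function(r) all(r == 0))
  if (any(flat)) {
    stop("constant (zero-variance) signal for ROI: ",
         paste(s$roi_labels[flat], collapse = ", "), call. = FALSE)
  }
  ph <- Arg(analytic_signal(x))
  rownames(ph) <- s$roi_labels
  ph
}

trim_index <- function(n, trim) {
  k <- floor(n * trim)
  seq.int(k + 1L, n - k)
}

#' Phase-locking value of two phase series
#'
#' The PLV is the modulus of the time-averaged complex phasor of the phase
#' difference. It equals 1 for perfectly locked series (any fixed offset) and
#' tends to 0 for independent phases. The first and last `trim` fraction of
#' samples are excluded to avoid analytic-signal edge transients.
#'
#' @param phase_u,phase_v numeric phase vectors of equal length
#' @param trim fraction of samples dropped at each end (default 0.05)
#' @return a value in `[0, 1]`
#' @export
plv <- function(phase_u, phase_v, trim = 0.05) {
  if (length(phase_u) != length(phase_v)) stop("length mismatch", call. = FALSE)
  if (length(phase_u) < 2L) stop("need at least 2 samples", call. = FALSE)
  idx <- trim_index(length(phase_u), trim)
  Mod(mean(exp(-1i * (phase_u[idx] - phase_v[idx]))))
}

#' Construct a PLV matrix object
#' @param values symmetric numeric matrix in `[0, 1]` with unit diagonal
#' @param roi_labels row/column labels
#' @export
plv_matrix_obj <- function(values, roi_labels = rownames(values)) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values))
  if (is.null(roi_labels)) stop("roi_labels required", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-8) stop("matrix not symmetric", call. = FALSE)
  if (any(values < -1e-12 | values > 1 + 1e-12)) stop("entries outside [0, 1]", call. = FALSE)
  values <- (values + t(values)) / 2
  diag(values) <- 1
  dimnames(values) <- list(roi_labels, roi_labels)
  structure(list(values = values, roi_labels = roi_labels), class = "plv_matrix")
}

#' @export
print.plv_matrix <- function(x, ...) {
  cat(sprintf("<plv_matrix> %d ROIs\n", length(x$roi_labels)))
  print(round(x$values, 3))
  invisible(x)
}

#' Pairwise PLV matrix of a signal set
#'
#' @param s a `signal_set` with at least two ROIs
#' @param trim edge-trim fraction passed to [plv()]
#' @return a `plv_matrix`
#' @export
plv_matrix <- function(s, trim = 0.05) {
  if (!inherits(s, "signal_set")) stop("expected a `signal_set`", call. = FALSE)
  if (nrow(s$values) < 2L) stop("need at least 2 ROIs", call. = FALSE)
  ph <- instantaneous_phase(s)
  idx <- trim_index(ncol(ph), trim)
  E <- exp(1i * ph[, idx, drop = FALSE])
  m <- Mod(E %*% Conj(t(E))) / length(idx)
  plv_matrix_obj(pmin(m, 1), s$roi_labels)
}

#' @export
tidy.plv_matrix <- function(x, ...) {
  n <- length(x$roi_labels)
  ut <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(roi_a = x$roi_labels[ut[, 1L]],
                 roi_b = x$roi_labels[ut[, 2L]],
                 plv = x$values[ut])
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.plv_matrix <- function(object, ...) {
  df <- expand.grid(roi_a = object$roi_labels, roi_b = object$roi_labels,
                    stringsAsFactors = FALSE)
  df$plv <- as.vector(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roi_a, y = .data$roi_b,
                                   fill = .data$plv)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "PLV") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Surrogate permutation test for PLV significance
#'
#' Builds a null distribution by surrogate signals: each ROI row is circularly
#' shifted by an independent random offset and time-reversed with probability
#' 1/2, which approximately preserves each signal's spectrum and
#' autocorrelation while destroying cross-ROI phase alignment. Per-pair
#' one-tailed p-values come from the empirical tail; family-wise control uses
#' the null distribution of the maximum PLV across pairs (a pair is flagged
#' when its observed PLV exceeds the `1 - alpha` point of that maximum
#' distribution, i.e. its FWE-corrected p-value is at most `alpha`).
#'
#' @param s a `signal_set`
#' @param n_perm number of surrogates (>= 100; the study setting is 1000)
#' @param alpha family-wise error level
#' @param seed optional RNG seed for reproducible surrogates
#' @param trim edge-trim fraction passed to the PLV average
#' @param tail `"empirical"` (default) or `"gpd"`, which refines small
#'   per-pair p-values with a generalized-Pareto fit to the null tail
#' @return list with `observed` (`plv_matrix`), `p` (per-pair matrix),
#'   `p_fwe` (max-statistic corrected), `mask` (logical significance matrix)
#'   and `max_null` (the permutation maximum distribution)
#' @export
surrogate_significance <- function(s, n_perm = 1000L, alpha = 0.05, seed = NULL,
                                   trim = 0.05, tail = c("empirical", "gpd")) {
  tail <- match.arg(tail)
  if (!inherits(s, "signal_set")) stop("expected a `signal_set`", call. = FALSE)
  if (n_perm < 100L) stop("n_perm < 100 gives an unstable null tail", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- s$values
  n <- nrow(x); T <- ncol(x)
  obs <- plv_matrix(s, trim = trim)
  off <- which(upper.tri(obs$values))
  cnt <- matrix(0, n, n)
  max_null <- numeric(n_perm)
  idx <- trim_index(T, trim)
  for (b in seq_len(n_perm)) {
    shifts <- sample.int(T, n, replace = TRUE) - 1L
    rev_flag <- stats::runif(n) < 0.5
    xs <- x
    for (i in seq_len(n)) {
      r <- if (rev_flag[i]) rev(x[i, ]) else x[i, ]
      if (shifts[i] > 0L) r <- c(r[(shifts[i] + 1L):T], r[1:shifts[i]])
      xs[i, ] <- r
    }
    ph <- Arg(analytic_signal(xs - rowMeans(xs)))
    E <- exp(1i * ph[, idx, drop = FALSE])
    m <- Mod(E %*% Conj(t(E))) / length(idx)
    cnt <- cnt + (m >= obs$values - 1e-15)
    max_null[b] <- max(m[off])
  }
  p <- (cnt + 1) / (n_perm + 1)
  if (tail == "gpd") {
    for (k in off) {
      p[k] <- gpd_tail_p(obs$values[k], max_null, p[k])
    }
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  p_fwe <- matrix((vapply(as.vector(obs$values),
                          function(v) sum(max_null >= v - 1e-15), 0) + 1) /
                    (n_perm + 1), n, n)
  diag(p) <- diag(p_fwe) <- NA_real_
  mask <- p_fwe <= alpha
  diag(mask) <- FALSE
  dimnames(p) <- dimnames(p_fwe) <- dimnames(mask) <-
    list(s$roi_labels, s$roi_labels)
  list(observed = obs, p = p, p_fwe = p_fwe, mask = mask, max_null = max_null)
}

# probability-weighted-moments fit of a generalized Pareto distribution to the
# exceedances over an upper threshold; returns a smoothed tail p-value
gpd_tail_p <- function(value, null, p_emp, n_exceed = 250L) {
  null <- sort(null, decreasing = TRUE)
  n_exceed <- min(n_exceed, floor(length(null) / 4))
  if (n_exceed < 20L) return(p_emp)
  thr <- null[n_exceed + 1L]
  if (value <= thr) return(p_emp)
  y <- sort(null[seq_len(n_exceed)] - thr)
  m <- length(y)
  b0 <- mean(y)
  b1 <- sum((seq_len(m) - 1) / (m - 1) * y) / m
  k <- b0 / (b0 - 2 * b1) - 2          # shape (Hosking & Wallis 1987)
  a <- 2 * b0 * b1 / (b0 - 2 * b1)     # scale
  z <- value - thr
  tail_prob <- if (abs(k) < 1e-9) exp(-z / a) else {
    inner <- 1 - k * z / a
    if (inner <= 0) 0 else inner^(1 / k)
  }
  max(n_exceed / length(null) * tail_prob, 1 / (length(null) + 1))
}

#' Entrywise average of PLV matrices across subjects
#'
#' @param mats list of `plv_matrix` objects with identical label order
#' @return a `plv_matrix`
#' @export
group_average <- function(mats) {
  if (!length(mats)) stop("need at least one matrix", call. = FALSE)
  labs <- mats[[1L]]$roi_labels
  for (m in mats) {
    if (!identical(m$roi_labels, labs)) stop("ROI label mismatch", call. = FALSE)
  }
  avg <- Reduce(`+`, lapply(mats, `[[`, "values")) / length(mats)
  plv_matrix_obj(avg, labs)
}

#' Read / write a PLV matrix as square CSV with labelled rows and columns
#' @param path file path
#' @export
load_plv_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  plv_matrix_obj(as.matrix(df), rownames(df))
}

#' @rdname load_plv_matrix
#' @param m a `plv_matrix`
#' @export
write_plv_matrix <- function(m, path) {
  utils::write.csv(data.frame(m$values, check.names = FALSE,
                              row.names = m$roi_labels), path)
  invisible(path)
}

#' Read / write ROI signals as CSV (label column then time columns) with an
#' optional JSON metadata sidecar carrying `tr_seconds`
#' @param path file path
#' @export
load_signals <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labs <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  meta_path <- sub("\\.[^.]+$", ".json", path)
  tr <- 2.5
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$tr_seconds)) tr <- meta$tr_seconds
  }
  signal_set(vals, labs, tr_seconds = tr)
}

#' @rdname load_signals
#' @param s a `signal_set`
#' @param meta optional list written to the JSON sidecar
#' @export
write_signals <- function(s, path, meta = list()) {
  df <- data.frame(roi = s$roi_labels, s$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta$tr_seconds <- s$tr_seconds
  jsonlite::write_json(meta, sub("\\.[^.]+$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}
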