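# Functional connectivity between EEG channels, and the class-conditioned
# ("task-specific") adjacency pairs built from it.

#' Connectivity estimation settings
#'
#' Bundles the options shared by the spectral/phase connectivity measures.
#'
#' @param method one of `"Cor"`, `"Coh"`, `"PLV"`, `"PLI"`.
#' @param band two-sided frequency band `c(lo_hz, hi_hz)` used by the
#'   spectral and phase methods (ignored by `"Cor"`).
#' @param welch_seg_s Welch segment length in seconds (coherence only).
#' @param welch_overlap Welch segment overlap fraction in `[0, 1)`.
#' @param edge_trim_s seconds discarded at each end of the phase series to
#'   suppress filter and analytic-transform transients (PLV/PLI only).
#' @return A list of class `conn_spec`.
#' @export
conn_spec <- function(method = c("PLV", "Cor", "Coh", "PLI"),
                      band = c(4, 45), welch_seg_s = 1,
                      welch_overlap = 0.5, edge_trim_s = 1) {
  method <- match.arg(method)
  stopifnot(length(band) == 2L, band[1] > 0, band[2] > band[1],
            welch_seg_s > 0, welch_overlap >= 0, welch_overlap < 1,
            edge_trim_s >= 0)
  structure(list(method = method, band = as.numeric(band),
                 welch_seg_s = welch_seg_s, welch_overlap = welch_overlap,
                 edge_trim_s = edge_trim_s),
            class = "conn_spec")
}

# Analytic signal via the frequency-domain Hilbert construction.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Instantaneous phases (C x N) after band-pass and edge trimming.
instantaneous_phases <- function(segment, spec) {
  if (n_samples(segment) / segment$fs < 3 && spec$edge_trim_s > 0)
    stop(sprintf("segment '%s' shorter than 3 s: too short for phase estimation (%.3g s)",
                 segment$trial_id, n_samples(segment) / segment$fs))
  filtered <- eeg_bandpass(segment, spec$band[1], spec$band[2])
  trim <- round_half_up(spec$edge_trim_s * segment$fs)
  keep <- (trim + 1L):(n_samples(segment) - trim)
  phi <- t(apply(filtered$data, 1L, function(x) Arg(analytic_signal(x))))
  phi[, keep, drop = FALSE]
}

plv_from_phases <- function(phi) {
  E <- exp(1i * phi)
  M <- Mod(E %*% Conj(t(E))) / ncol(phi)
  M <- pmin(M, 1)
  dimnames(M) <- list(rownames(phi), rownames(phi))
  M
}

pli_from_phases <- function(phi) {
  C <- nrow(phi)
  M <- matrix(0, C, C, dimnames = list(rownames(phi), rownames(phi)))
  for (a in seq_len(C - 1L)) for (b in (a + 1L):C) {
    v <- abs(mean(sign(sin(phi[a, ] - phi[b, ]))))
    M[a, b] <- M[b, a] <- v
  }
  M
}

#' Pearson correlation connectivity
#'
#' Entry (a, b) is the Pearson correlation of channels a and b over time.
#' A zero-variance channel gets zero off-diagonal entries (with a warning)
#' rather than an error.
#'
#' @param segment an [eeg_trial()] or segment.
#' @return A symmetric C x C matrix with unit diagonal, entries in `[-1, 1]`.
#' @export
pearson_matrix <- function(segment) {
  stopifnot(inherits(segment, "eeg_trial"))
  sds <- apply(segment$data, 1L, stats::sd)
  M <- suppressWarnings(stats::cor(t(segment$data)))
  if (any(sds == 0)) {
    warning("zero-variance channel(s): ",
            paste(segment$channels[sds == 0], collapse = ", "),
            "; their correlations set to 0")
    M[sds == 0, ] <- 0
    M[, sds == 0] <- 0
  }
  diag(M) <- 1
  M
}

# Welch cross-spectral density array: nbins x C x C (complex), plus the bin
# frequencies.  Hann window, per-segment demeaning.
welch_csd <- function(data, fs, seg_len, overlap) {
  C <- nrow(data); T_len <- ncol(data)
  if (seg_len > T_len)
    stop("segment shorter than one Welch segment")
  step <- max(1L, round_half_up(seg_len * (1 - overlap)))
  starts <- seq.int(1L, T_len - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq.int(0L, seg_len - 1L) / (seg_len - 1L))
  nbins <- seg_len %/% 2 + 1L
  S <- array(0i, dim = c(nbins, C, C))
  for (s in starts) {
    blk <- data[, s:(s + seg_len - 1L), drop = FALSE]
    blk <- sweep(blk, 1L, rowMeans(blk))
    Fm <- stats::mvfft(t(blk * rep(w, each = C)))[seq_len(nbins), ,
                                                  drop = FALSE]
    for (f in seq_len(nbins))
      S[f, , ] <- S[f, , ] + outer(Fm[f, ], Conj(Fm[f, ]))
  }
  list(S = S / length(starts),
       freq = (seq_len(nbins) - 1L) * fs / seg_len)
}

#' Magnitude-squared coherence connectivity
#'
#' Welch cross-spectral estimates (Hann window) give per-frequency
#' magnitude-squared coherence `|S_ab|^2 / (S_aa S_bb)`; the matrix entry is
#' the unweighted mean over frequency bins inside `spec$band`.
#'
#' @param segment an [eeg_trial()] or segment.
#' @param spec a [conn_spec()].
#' @return A symmetric C x C matrix with entries in `[0, 1]`.
#' @export
coherence_matrix <- function(segment, spec = conn_spec("Coh")) {
  stopifnot(inherits(segment, "eeg_trial"))
  seg_len <- round_half_up(spec$welch_seg_s * segment$fs)
  cs <- welch_csd(segment$data, segment$fs, seg_len, spec$welch_overlap)
  in_band <- which(cs$freq >= spec$band[1] & cs$freq <= spec$band[2])
  if (!length(in_band))
    stop(sprintf("no frequency bins inside [%g, %g] Hz",
                 spec$band[1], spec$band[2]))
  C <- nrow(segment$data)
  M <- matrix(0, C, C, dimnames = list(segment$channels, segment$channels))
  for (a in seq_len(C)) for (b in seq_len(C)) {
    num <- Mod(cs$S[in_band, a, b])^2
    den <- Re(cs$S[in_band, a, a]) * Re(cs$S[in_band, b, b])
    M[a, b] <- mean(num / den)
  }
  (M + t(M)) / 2
}

#' Phase locking value connectivity
#'
#' Channels are band-passed, instantaneous phases extracted from the
#' analytic signal (1 s discarded at each edge by default), and entry
#' (a, b) is `|mean(exp(1i * (phi_a - phi_b)))|`: 1 for perfect phase
#' locking, near 0 for random phase differences.
#'
#' @inheritParams coherence_matrix
#' @return A symmetric C x C matrix with unit diagonal, entries in `[0, 1]`.
#' @export
plv_matrix <- function(segment, spec = conn_spec("PLV")) {
  stopifnot(inherits(segment, "eeg_trial"))
  plv_from_phases(instantaneous_phases(segment, spec))
}

#' Phase lag index connectivity
#'
#' As [plv_matrix()] but entry (a, b) is
#' `|mean(sign(sin(phi_a - phi_b)))|`: the asymmetry of the phase-difference
#' sign.  0 for zero lag (or symmetric lags), 1 for a consistent lag; the
#' diagonal is 0.
#'
#' @inheritParams coherence_matrix
#' @return A symmetric C x C matrix with zero diagonal, entries in `[0, 1]`.
#' @export
pli_matrix <- function(segment, spec = conn_spec("PLI")) {
  stopifnot(inherits(segment, "eeg_trial"))
  pli_from_phases(instantaneous_phases(segment, spec))
}

#' Connectivity matrix for a segment, by method
#'
#' @inheritParams coherence_matrix
#' @return A C x C connectivity matrix for `spec$method`.
#' @export
connectivity_matrix <- function(segment, spec) {
  switch(spec$method,
         Cor = pearson_matrix(segment),
         Coh = coherence_matrix(segment, spec),
         PLV = plv_matrix(segment, spec),
         PLI = pli_matrix(segment, spec))
}

#' Select trials or segments by class label
#'
#' @param x list of [eeg_trial()] objects (or segments).
#' @param label class label to keep.
#' @return The matching subset, order preserved.
#' @export
select_by_label <- function(x, label) {
  labs <- vapply(x, function(tr) tr$label, "")
  if (!label %in% labs)
    stop(sprintf("class '%s' has no training data", label))
  x[labs == label]
}

#' Symmetric normalization of an adjacency matrix
#'
#' Computes `D^(-1/2) A D^(-1/2)` with `D_aa = sum_b A_ab`, the standard
#' pre-conditioning for graph convolution.
#'
#' @param A symmetric nonnegative matrix with positive row sums.
#' @return The normalized matrix, same dimnames.
#' @export
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  if (max(abs(A - t(A))) > 1e-8) stop("adjacency must be symmetric")
  if (any(A < 0)) stop("adjacency must be nonnegative")
  d <- rowSums(A)
  if (any(d <= 0)) {
    bad <- which(d <= 0)
    nm <- rownames(A)[bad] %||% as.character(bad)
    stop("zero row sum for channel(s): ", paste(nm, collapse = ", "))
  }
  A / sqrt(outer(d, d))
}

# Assemble a task_adjacency object from per-segment connectivity matrices.
task_adjacency_from_mats <- function(mats, seg_labels, labels, method,
                                     source_ids = NULL) {
  if (!all(labels %in% seg_labels)) {
    missing <- setdiff(labels, seg_labels)
    stop("class(es) with no training segments: ",
         paste(missing, collapse = ", "))
  }
  adj <- lapply(labels, function(l) {
    ms <- mats[seg_labels == l]
    if (method == "Cor") ms <- lapply(ms, abs)  # per segment, before mean
    M <- Reduce(`+`, ms) / length(ms)
    diag(M) <- 1
    M
  })
  names(adj) <- labels
  structure(list(method = method, labels = labels, adj = adj,
                 norm = lapply(adj, normalize_adjacency),
                 source_ids = source_ids),
            class = "task_adjacency")
}

#' Build a pair of task-specific adjacency matrices
#'
#' For each class label, the adjacency is the element-wise mean of the
#' per-segment connectivity matrices over that class's training segments
#' (absolute value first for correlation, whose raw entries may be
#' negative), with the diagonal then fixed to 1 (self-loops) and the result
#' symmetric-normalized.  Both classes must be present; training segments
#' only should be supplied -- the matrices define the model and must never
#' see validation or test data.
#'
#' @param segments list of training segments.
#' @param spec a [conn_spec()].
#' @param labels the two class labels in order `c(l1, l2)`; defaults to the
#'   sorted unique labels present.
#' @return An object of class `task_adjacency` with elements `method`,
#'   `labels`, `adj` (raw averaged matrices) and `norm` (their
#'   symmetric-normalized forms), one per class.
#' @export
build_task_adjacency <- function(segments, spec, labels = NULL) {
  seg_labels <- vapply(segments, function(s) s$label, "")
  if (is.null(labels)) labels <- sort(unique(seg_labels))
  if (length(labels) != 2L) stop("exactly two class labels are required")
  mats <- lapply(segments, connectivity_matrix, spec = spec)
  ids <- vapply(segments, function(s) s$parent_trial_id %||% s$trial_id, "")
  task_adjacency_from_mats(mats, seg_labels, labels, spec$method,
                           source_ids = unique(ids))
}

#' @export
print.task_adjacency <- function(x, ...) {
  cat(sprintf("<task_adjacency> method %s, %d channels, classes %s / %s\n",
              x$method, nrow(x$adj[[1]]), x$labels[1], x$labels[2]))
  invisible(x)
}
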