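#' Configuration for the phase-locked signal generator
#'
#' Defaults mirror the acquisition this package emulates: 11 ROIs, 160
#' volumes at TR = 2.5 s, 20 subjects, band-limited phase dynamics in
#' 0.01-0.1 Hz, and a von Mises within-cluster phase jitter with
#' concentration `kappa`.
#'
#' @param n_rois number of ROIs
#' @param n_timepoints time points per subject (>= 16)
#' @param tr_seconds sampling interval (s)
#' @param n_subjects subjects per condition
#' @param band lower/upper band edge in Hz; must sit below Nyquist
#' @param kappa von Mises concentration of within-cluster phase jitter
#'   (`Inf` = perfectly locked)
#' @param noise_sd standard deviation of additive signal noise
#' @param seed RNG seed used by the generators
#' @return a list of class `generator_config`
#' @export
generator_config <- function(n_rois = 11L, n_timepoints = 160L,
                             tr_seconds = 2.5, n_subjects = 20L,
                             band = c(0.01, 0.1), kappa = 10,
                             noise_sd = 0.05, seed = 1L) {
  if (n_timepoints < 16L) stop("n_timepoints must be >= 16", call. = FALSE)
  nyq <- 1 / (2 * tr_seconds)
  if (!(band[1L] > 0 && band[1L] < band[2L] && band[2L] < nyq)) {
    stop("band must satisfy 0 < low < high < Nyquist = ", nyq, " Hz",
         call. = FALSE)
  }
  structure(list(n_rois = n_rois, n_timepoints = n_timepoints,
                 tr_seconds = tr_seconds, n_subjects = n_subjects,
                 band = band, kappa = kappa, noise_sd = noise_sd, seed = seed),
            class = "generator_config")
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler; `kappa = Inf` returns zeros and
#' `kappa = 0` the uniform circle.
#'
#' @param n number of draws
#' @param kappa concentration parameter (>= 0)
#' @return angles in (-pi, pi]
#' @export
rvonmises <- function(n, kappa) {
  if (kappa < 0) stop("kappa must be non-negative", call. = FALSE)
  if (is.infinite(kappa)) return(numeric(n))
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 16L)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, sign(u3[ok] - 0.5) * acos(f[ok]))
  }
  out[seq_len(n)]
}

# band-limited latent analytic signal: random complex Fourier coefficients on
# the in-band positive-frequency bins only; the latent phase is Arg of this
latent_analytic <- function(n_t, tr, band) {
  freqs <- (seq_len(n_t) - 1L) / (n_t * tr)
  bins <- which(freqs >= band[1L] & freqs <= band[2L] & freqs <= 1 / (2 * tr))
  coef <- complex(real = stats::rnorm(length(bins)),
                  imaginary = stats::rnorm(length(bins)))
  X <- complex(real = numeric(n_t), imaginary = numeric(n_t))
  X[bins] <- coef
  z <- stats::fft(X, inverse = TRUE)
  z / sqrt(mean(Mod(z)^2))
}

#' Generate phase-locked BOLD-like signal sets
#'
#' For each colour class of `coloring`, a latent in-band random phase process
#' is drawn; each member's phase is the latent phase plus independent von
#' Mises jitter (concentration `kappa`) plus a fixed member offset, and its
#' signal is the latent-amplitude-modulated cosine of that phase plus
#' additive Gaussian noise (keeping the latent amplitude makes the analytic
#' signal recover the planted phase exactly, so `kappa = Inf`,
#' `noise_sd = 0` gives within-cluster PLV of exactly 1). Distinct classes
#' use independent latents, so within-class pairs phase-lock and cross-class
#' pairs do not. One `signal_set` is produced per subject; subjects share the
#' cluster structure but not the latent phases.
#'
#' @param coloring a `roi_coloring` defining the planted clusters
#' @param cfg a `generator_config`; `cfg$seed` seeds the RNG
#' @return list of `signal_set`, one per subject
#' @export
generate_phase_locked_signals <- function(coloring, cfg = generator_config()) {
  if (!inherits(cfg, "generator_config")) stop("expected a `generator_config`",
                                               call. = FALSE)
  set.seed(cfg$seed)
  rois <- unlist(coloring$classes, use.names = FALSE)
  n_t <- cfg$n_timepoints
  offsets <- stats::setNames(stats::runif(length(rois), -pi, pi), rois)
  lapply(seq_len(cfg$n_subjects), function(subj) {
    vals <- matrix(0, length(rois), n_t, dimnames = list(rois, NULL))
    for (cl in coloring$classes) {
      z <- latent_analytic(n_t, cfg$tr_seconds, cfg$band)
      for (v in cl) {
        jitter <- rvonmises(n_t, cfg$kappa)
        vals[v, ] <- Re(z * exp(1i * (jitter + offsets[[v]]))) +
          stats::rnorm(n_t, sd = cfg$noise_sd)
      }
    }
    signal_set(vals, rois, tr_seconds = cfg$tr_seconds)
  })
}

#' Random lift of a base graph with prescribed fiber sizes
#'
#' Expands each base node into a fiber of the requested size; for every base
#' arc s -> t, each copy of t receives exactly one in-arc from a uniformly
#' chosen copy of s (the unique-lifting property), so the planted coloring is
#' balanced on the lift by construction.
#'
#' @param base a `connectome`
#' @param fiber_sizes named integer vector (base node -> positive size)
#' @param seed RNG seed
#' @return list with `graph` (the lift `connectome`) and `coloring` (the
#'   planted `roi_coloring`)
#' @export
generate_fibration_lift <- function(base, fiber_sizes, seed = 1L) {
  stopifnot_connectome(base)
  fiber_sizes <- fiber_sizes[base$nodes]
  if (anyNA(fiber_sizes) || any(fiber_sizes < 1L)) {
    stop("fiber_sizes must give a positive size for every base node",
         call. = FALSE)
  }
  set.seed(seed)
  copies <- lapply(base$nodes, function(v) paste0(v, "_", seq_len(fiber_sizes[[v]])))
  names(copies) <- base$nodes
  arcs <- list()
  for (i in seq_len(nrow(base$arcs))) {
    s <- base$arcs$from[i]; t <- base$arcs$to[i]
    src <- copies[[s]][sample.int(length(copies[[s]]), length(copies[[t]]),
                                  replace = TRUE)]
    arcs[[length(arcs) + 1L]] <- tibble::tibble(from = src, to = copies[[t]])
  }
  g <- connectome(dplyr::bind_rows(arcs), nodes = unlist(copies), directed = TRUE)
  list(graph = g, coloring = roi_coloring(copies))
}

#' Simulate admissible phase-oscillator dynamics on a connectome
#'
#' Integrates a Kuramoto-type system in which every node is driven
#' identically by the multiset of its in-neighbours' states,
#' `dx_i/dt = omega + coupling * sum_j sin(x_j - x_i)` over in-neighbours j.
#' Such dynamics are admissible for the graph, so trajectories initialized
#' equal within each fiber remain equal for the whole horizon
#' (fiber synchrony / flow invariance of the cluster subspace).
#'
#' @param g a `connectome`
#' @param init named numeric vector of initial states (one per node)
#' @param params list with `omega` (drift) and `coupling`
#' @param horizon integration end time
#' @param dt fixed integration step (classical Runge-Kutta)
#' @return matrix (node x time) of trajectories; attribute `times`
#' @export
simulate_admissible_dynamics <- function(g, init,
                                         params = list(omega = 1, coupling = 0.4),
                                         horizon = 20, dt = 0.05) {
  stopifnot_connectome(g)
  if (!all(g$nodes %in% names(init))) stop("init must cover every node", call. = FALSE)
  init <- init[g$nodes]
  inn <- in_neighbours(g)
  idx <- lapply(inn, function(v) match(v, g$nodes))
  deriv <- function(t, x, p) {
    dx <- vapply(seq_along(x), function(i) {
      p$omega + p$coupling * sum(sin(x[idx[[i]]] - x[i]))
    }, 0)
    list(dx)
  }
  times <- seq(0, horizon, by = dt)
  sol <- deSolve::ode(y = init, times = times, func = deriv, parms = params,
                      method = "rk4")
  traj <- t(sol[, -1L, drop = FALSE])
  if (any(!is.finite(traj))) {
    stop("non-finite state encountered during integration (step size ", dt, ")",
         call. = FALSE)
  }
  rownames(traj) <- g$nodes
  attr(traj, "times") <- times
  traj
}

# printed Cluster-PLV hierarchies used as worked-example fixtures
printed_cs_tables <- function() {
  list(
    rest = list(
      cliques = list(
        list(members = c("SMG_L", "SMG_R"), plv = 0.762),
        list(members = c("PreMA_L", "PreMA_R", "SMA", "WA_L", "WA_R"), plv = 0.712),
        list(members = c("AG_L", "AG_R"), plv = 0.689),
        list(members = c("BA_L", "BA_R"), plv = 0.689)),
      links = list(
        list(a = "AG_R", b = "WA_R", plv = 0.682),
        list(a = "BA_L", b = "SMA", plv = 0.662),
        list(a = "SMG_R", b = "PreMA_L", plv = 0.639))),
    verb = list(
      cliques = list(
        list(members = c("SMA", "BA_L"), plv = 0.764),
        list(members = c("PreMA_L", "PreMA_R"), plv = 0.625),
        list(members = c("AG_L", "AG_R"), plv = 0.624),
        list(members = c("WA_L", "WA_R", "BA_R"), plv = 0.560),
        list(members = c("SMG_L", "SMG_R"), plv = 0.538)),
      links = list()),
    phonemic = list(
      cliques = list(
        list(members = c("SMA", "BA_L"), plv = 0.725),
        list(members = c("AG_L", "AG_R"), plv = 0.699),
        list(members = c("PreMA_L", "PreMA_R"), plv = 0.595),
        list(members = c("WA_L", "WA_R", "BA_R"), plv = 0.570),
        list(members = c("SMG_L", "SMG_R"), plv = 0.550)),
      links = list()))
}

#' ROI labels of the dorsal-stream language network
#' @export
language_rois <- function() {
  c("SMA", "PreMA_L", "PreMA_R", "BA_L", "BA_R", "AG_L", "AG_R",
    "WA_L", "WA_R", "SMG_L", "SMG_R")
}

#' Synthetic PLV matrix reproducing a printed cluster hierarchy
#'
#' Builds an 11-ROI PLV matrix in which every intra-clique entry of each
#' reported cluster-synchronization clique equals that clique's reported
#' Cluster PLV, each reported inter-clique link takes its reported value, and
#' all remaining entries are distinct filler values in `[0.20, 0.40]` (seeded
#' random assignment of an evenly spaced grid; mutual distinctness avoids
#' spurious percolation ties).
#'
#' @param condition `"rest"`, `"phonemic"` or `"verb"`
#' @param filler_seed seed for the filler assignment
#' @return a `plv_matrix`
#' @export
build_printed_plv_fixture <- function(condition = c("rest", "phonemic", "verb"),
                                      filler_seed = 1L) {
  condition <- match.arg(condition)
  tab <- printed_cs_tables()[[condition]]
  rois <- language_rois()
  n <- length(rois)
  m <- matrix(NA_real_, n, n, dimnames = list(rois, rois))
  diag(m) <- 1
  for (cl in tab$cliques) {
    for (a in cl$members) for (b in cl$members) {
      if (a != b) m[a, b] <- cl$plv
    }
  }
  for (lk in tab$links) {
    m[lk$a, lk$b] <- m[lk$b, lk$a] <- lk$plv
  }
  ut <- which(upper.tri(m) & is.na(m), arr.ind = TRUE)
  fill <- seq(0.20, 0.40, length.out = nrow(ut))
  set.seed(filler_seed)
  fill <- sample(fill)
  for (i in seq_len(nrow(ut))) {
    m[ut[i, 1L], ut[i, 2L]] <- m[ut[i, 2L], ut[i, 1L]] <- fill[i]
  }
  plv_matrix_obj(m, rois)
}

# printed reference partitions of the baseline connectome
baseline_printed_partitions <- function() {
  fibers <- roi_coloring(list(
    c("PreMA_L", "PreMA_R"), c("BA_L", "BA_R"), c("AG_L", "AG_R"),
    c("WA_L", "WA_R", "SMG_L", "SMG_R"), "SMA"))
  list(fibers = fibers, orbits = fibers)
}

#' The packaged dorsal-stream baseline connectome
#'
#' Loads the 11-ROI, 22-tract baseline connectome of the language network
#' (FAT, SMA-premotor connections, arcuate fasciculus / dorsal pathway II,
#' dorsal pathway I, SLF attachments to supramarginal and angular gyri, local
#' parietal-temporal links, and callosal homotopic edges for Broca's area and
#' the angular gyrus), transcribed from the published network diagrams.
#' Undirected tracts are expanded to reciprocal arc pairs.
#'
#' At load time the fixture is validated against the published symmetry
#' analysis: its fiber partition and its orbit partition must both equal the
#' five reported classes, and the mirror permutation and the WA/SMG swap must
#' be automorphisms. Any transcription corruption raises an error.
#'
#' @param validate run the validation gate (default `TRUE`)
#' @return a `connectome`
#' @export
baseline_connectome <- function(validate = TRUE) {
  path <- system.file("extdata", "baseline_connectome.tsv", package = "fibrasym")
  g <- load_edge_list(path, directed = FALSE)
  g <- connectome(g$arcs, nodes = language_rois(), directed = TRUE)
  g$directed_input <- FALSE
  if (validate) {
    ref <- baseline_printed_partitions()
    fib <- minimal_balanced_coloring(g)
    if (!same_partition(fib, ref$fibers)) {
      stop("baseline fixture corrupt: fiber partition differs from the ",
           "published five fibers", call. = FALSE)
    }
    grp <- enumerate_automorphisms(g)
    orb <- orbit_partition(grp, g)
    if (!same_partition(orb, ref$orbits)) {
      stop("baseline fixture corrupt: orbit partition differs from the ",
           "published five orbits", call. = FALSE)
    }
    pi1 <- mirror_permutation()
    pi2 <- wa_smg_swap()
    keys <- vapply(grp$elements, function(p) paste(p, collapse = "\r"), "")
    if (!paste(pi1[g$nodes], collapse = "\r") %in% keys ||
        !paste(pi2[g$nodes], collapse = "\r") %in% keys) {
      stop("baseline fixture corrupt: published generators are not ",
           "automorphisms", call. = FALSE)
    }
  }
  g
}

#' Published reference permutations of the language network
#'
#' `mirror_permutation()` swaps every left/right homologue; `wa_smg_swap()`
#' exchanges Wernicke's area and the supramarginal gyrus within each
#' hemisphere.
#' @return named character vector mapping node to image
#' @export
mirror_permutation <- function() {
  rois <- language_rois()
  p <- stats::setNames(rois, rois)
  for (b in c("PreMA", "BA", "AG", "WA", "SMG")) {
    p[paste0(b, "_L")] <- paste0(b, "_R")
    p[paste0(b, "_R")] <- paste0(b, "_L")
  }
  p
}

#' @rdname mirror_permutation
#' @export
wa_smg_swap <- function() {
  rois <- language_rois()
  p <- stats::setNames(rois, rois)
  p[c("WA_L", "SMG_L", "WA_R", "SMG_R")] <- c("SMG_L", "WA_L", "SMG_R", "WA_R")
  p
}
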