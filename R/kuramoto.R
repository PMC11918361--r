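# Connectivity construction, Kuramoto simulation, virtual slicing and the
# deviation statistics quantifying slicing damage.

#' Build a neuron connectivity graph
#'
#' Distance connectivity plus random long-range connections: neurons within
#' `radius` micrometres (Euclidean) are connected, then every unordered
#' non-adjacent pair is independently added with probability `q`. The result
#' is a symmetric 0/1 adjacency with zero diagonal.
#'
#' @param table an [scn_neuron_table()].
#' @param radius connection radius in micrometres (default 20).
#' @param q probability of a random connection between any two neurons
#'   (default 0).
#' @param seed RNG seed for the random edges.
#' @return an object of class `scn_graph`: sparse `adjacency`
#'   (`Matrix::dgCMatrix`), neuron `ids`, and a construction `record`.
#' @export
build_connectivity <- function(table, radius = 20, q = 0, seed = 1L) {
  stopifnot(inherits(table, "scn_neuron_table"))
  if (radius <= 0)
    stop_scn("radius must be positive", class = "scn_config_error")
  if (q < 0 || q > 1)
    stop_scn("q must lie in [0, 1]", class = "scn_config_error")
  n <- nrow(table)
  xyz <- neuron_coords(table)
  pr <- radius_pairs_cpp(xyz[, 1], xyz[, 2], xyz[, 3], radius)
  di <- pr$i; dj <- pr$j
  n_dist <- length(di)

  ri <- integer(0); rj <- integer(0)
  if (q > 0 && n > 1) {
    set.seed(seed)
    key <- function(i, j) (pmin(i, j) - 1) * n + pmax(i, j)  # unordered key
    existing <- key(di, dj)
    m_all <- n * (n - 1) / 2
    if (q == 1) {
      all_ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      add <- key(all_ij[, 1], all_ij[, 2])
      add <- setdiff(add, existing)
    } else {
      m <- rbinom(1, m_all - n_dist, q)
      add <- integer(0)
      guard <- 0L
      while (length(add) < m && guard < 100L) {
        need <- m - length(add)
        ci <- sample.int(n, ceiling(need * 1.5), replace = TRUE)
        cj <- sample.int(n, ceiling(need * 1.5), replace = TRUE)
        ok <- ci != cj
        cand <- unique(key(ci[ok], cj[ok]))
        cand <- setdiff(cand, c(existing, add))
        add <- c(add, utils::head(cand, need))
        guard <- guard + 1L
      }
    }
    if (length(add) > 0) {
      ri <- ((add - 1) %/% n) + 1
      rj <- ((add - 1) %% n) + 1
    }
  }

  ii <- c(di, ri); jj <- c(dj, rj)
  adjacency <- Matrix::sparseMatrix(
    i = c(ii, jj), j = c(jj, ii), x = 1, dims = c(n, n)
  )
  structure(list(
    adjacency = adjacency, ids = table$neuron_id,
    record = list(radius = radius, q = q, seed = seed,
                  n_distance_edges = n_dist, n_random_edges = length(ri))
  ), class = "scn_graph")
}

#' @export
print.scn_graph <- function(x, ...) {
  cat(sprintf(
    "<scn_graph> %d neurons, %d distance edges (radius %g um) + %d random edges (q = %g)\n",
    length(x$ids), x$record$n_distance_edges, x$record$radius,
    x$record$n_random_edges, x$record$q
  ))
  invisible(x)
}

#' Induced subgraph on a subset of neurons
#'
#' Restriction of the adjacency to a slab keeps the surviving edges and
#' drops every edge with a removed endpoint; random edges are not resampled,
#' modelling physical cutting.
#'
#' @param graph an `scn_graph`.
#' @param idx integer positions (row indices) of the neurons to keep.
#' @return an `scn_graph` on the subset.
#' @export
induced_subgraph <- function(graph, idx) {
  stopifnot(inherits(graph, "scn_graph"))
  structure(list(
    adjacency = graph$adjacency[idx, idx, drop = FALSE],
    ids = graph$ids[idx],
    record = c(graph$record, list(subset_size = length(idx)))
  ), class = "scn_graph")
}

#' Simulate Kuramoto dynamics on a connectivity graph
#'
#' Integrates
#' \deqn{\dot\theta_i = \omega + K \sum_j A_{ij} \sin(\theta_j - \theta_i)}
#' with identical intrinsic frequencies (24-hour period) by classical
#' fourth-order Runge-Kutta at a fixed 30-second step, recording hourly
#' checkpoints. Phases are integrated unwrapped; wrapping is applied only in
#' order-parameter and deviation computations.
#'
#' @param theta0 initial phases in radians (length = number of neurons).
#' @param graph an `scn_graph`.
#' @param K coupling strength (>= 0).
#' @param omega intrinsic angular frequency, default `2 pi / 24` per hour.
#' @param dt_seconds integration step in seconds (default 30; must divide the
#'   checkpoint interval).
#' @param duration_hours simulated duration (default 24).
#' @param checkpoint_hours checkpoint spacing (default 1).
#' @return an object of class `scn_trajectory`: matrix `theta` of
#'   `(n_checkpoints + 1) x N` unwrapped phases, `times` in hours, and the
#'   configuration.
#' @export
simulate_kuramoto <- function(theta0, graph, K, omega = 2 * pi / 24,
                              dt_seconds = 30, duration_hours = 24,
                              checkpoint_hours = 1) {
  stopifnot(inherits(graph, "scn_graph"))
  n <- length(graph$ids)
  if (length(theta0) != n)
    stop_scn("theta0 length (", length(theta0),
             ") does not match the graph (", n, ")",
             class = "scn_mismatch_error")
  if (K < 0) stop_scn("K must be nonnegative", class = "scn_config_error")
  dt <- dt_seconds / 3600
  spc <- checkpoint_hours / dt
  if (abs(spc - round(spc)) > 1e-9)
    stop_scn("dt must divide the checkpoint spacing",
             class = "scn_config_error")
  ncp <- duration_hours / checkpoint_hours
  if (abs(ncp - round(ncp)) > 1e-9)
    stop_scn("checkpoint spacing must divide the duration",
             class = "scn_config_error")
  A <- methods::as(graph$adjacency, "CsparseMatrix")
  theta <- kuramoto_rk4_cpp(as.numeric(theta0), A@p, A@i, K, omega, dt,
                            as.integer(round(spc)), as.integer(round(ncp)))
  structure(list(
    theta = theta,
    times = seq(0, duration_hours, by = checkpoint_hours),
    K = K, omega = omega, dt_seconds = dt_seconds, ids = graph$ids
  ), class = "scn_trajectory")
}

#' @export
print.scn_trajectory <- function(x, ...) {
  cat(sprintf(
    "<scn_trajectory> %d oscillators, %d checkpoints over %g h (K = %g)\n",
    ncol(x$theta), length(x$times), max(x$times), x$K
  ))
  invisible(x)
}

#' Select neurons inside a virtual slab
#'
#' A virtual slice restricts the cloud to a slab of the given width centered
#' at the mean of one coordinate: coronal on y (rostral-caudal), sagittal on
#' x (medial-lateral), horizontal on z (dorsal-ventral). Boundary neurons
#' (|coordinate - mean| = width/2) are included.
#'
#' @param table an [scn_neuron_table()].
#' @param orientation `"coronal"`, `"sagittal"` or `"horizontal"`.
#' @param width slab width in micrometres (default 100).
#' @return integer row indices of the neurons inside the slab.
#' @export
virtual_slice <- function(table, orientation, width = 100) {
  stopifnot(inherits(table, "scn_neuron_table"))
  if (nrow(table) == 0)
    stop_scn("empty neuron table", class = "scn_config_error")
  orientation <- match.arg(orientation, SLICE_ORIENTATIONS)
  coord <- switch(orientation,
                  coronal = table$y_um,
                  sagittal = table$x_um,
                  horizontal = table$z_um)
  idx <- which(abs(coord - mean(coord)) <= width / 2)
  if (length(idx) == 0)
    stop_scn("empty slab: no neuron within the ", orientation, " slab",
             class = "scn_degenerate_error")
  idx
}

#' Deviation statistic between intact and sliced simulations
#'
#' The mean over slice neurons of the absolute principal-value angular
#' difference between the sliced and intact phases at the 24-hour
#' checkpoint:
#' \deqn{\frac{1}{|S|} \sum_{j \in S} \left| \arg e^{i(\hat\theta_{24,j} - \theta_{24,j})} \right| \in [0, \pi].}
#'
#' @param intact trajectory of the intact cloud.
#' @param sliced trajectory simulated on the induced slab subgraph with the
#'   same initial phases restricted to the slab.
#' @param slice_idx row indices of the slab neurons in the intact cloud.
#' @param at_hour checkpoint at which to compare (default 24).
#' @return the deviation in radians, with the per-neuron absolute
#'   differences attached as attribute `"differences"`.
#' @export
deviation_statistic <- function(intact, sliced, slice_idx, at_hour = 24) {
  stopifnot(inherits(intact, "scn_trajectory"),
            inherits(sliced, "scn_trajectory"))
  if (ncol(sliced$theta) != length(slice_idx) ||
      max(slice_idx) > ncol(intact$theta))
    stop_scn("slice index does not match the trajectories",
             class = "scn_mismatch_error")
  if (!identical(intact$ids[slice_idx], sliced$ids))
    stop_scn("sliced trajectory neurons do not match slice_idx",
             class = "scn_mismatch_error")
  row_i <- match(at_hour, intact$times)
  row_s <- match(at_hour, sliced$times)
  if (is.na(row_i) || is.na(row_s))
    stop_scn("no checkpoint at hour ", at_hour, class = "scn_mismatch_error")
  d <- abs(wrap_radians(sliced$theta[row_s, ] -
                          intact$theta[row_i, slice_idx]))
  out <- mean(d)
  attr(out, "differences") <- d
  out
}

#' Sweep slicing orientations over a (q, K) parameter grid
#'
#' For each pair on the grid: build the connectivity once (distance edges
#' plus q-random edges), simulate the intact cloud, then simulate each of
#' the three 100 um virtual slabs on its induced subgraph with the same
#' initial phases restricted to the slab, and record the deviation statistic
#' of each orientation. The winner of a cell is the orientation with the
#' highest deviation ("tie" when deviations are indistinguishable, e.g. at
#' K = 0 where all are exactly zero). Per-cell failures are flagged and the
#' sweep continues.
#'
#' @param table an [scn_neuron_table()].
#' @param theta0 initial phases in radians (e.g. calibrated snapshot
#'   estimates).
#' @param q_grid,K_grid parameter grids (defaults: q log-spaced over
#'   `[1e-4, 1e-1]`, K linear over `[0, 2]`, 4 points each).
#' @param radius connection radius in micrometres.
#' @param width slab width in micrometres.
#' @param seed base RNG seed; each q value uses `seed + index - 1` for its
#'   random edges, shared by every K and orientation in that column.
#' @param dt_seconds,duration_hours integrator settings.
#' @return an object of class `scn_sweep`: `results` data.frame (`q`, `K`,
#'   `orientation`, `deviation_radians`, `deviation_hours`, `winner`, `ok`),
#'   `winner` matrix over the grid, and `differences` (per-cell list of
#'   per-neuron absolute differences for CDF plots).
#' @export
orientation_sweep <- function(table, theta0,
                              q_grid = 10^seq(-4, -2, length.out = 4),
                              K_grid = seq(0, 2, length.out = 4),
                              radius = 20, width = 100, seed = 1L,
                              dt_seconds = 30, duration_hours = 24) {
  stopifnot(inherits(table, "scn_neuron_table"))
  if (length(q_grid) == 0 || length(K_grid) == 0)
    stop_scn("parameter grids must be nonempty", class = "scn_config_error")
  slabs <- lapply(stats::setNames(nm = SLICE_ORIENTATIONS), function(o)
    virtual_slice(table, o, width = width))
  winner <- matrix(NA_character_, length(q_grid), length(K_grid),
                   dimnames = list(paste0("q=", signif(q_grid, 3)),
                                   paste0("K=", signif(K_grid, 3))))
  results <- list()
  differences <- list()
  for (qi in seq_along(q_grid)) {
    q <- q_grid[qi]
    graph <- build_connectivity(table, radius = radius, q = q,
                                seed = seed + qi - 1L)
    subgraphs <- lapply(slabs, function(idx) induced_subgraph(graph, idx))
    for (ki in seq_along(K_grid)) {
      K <- K_grid[ki]
      cell <- tryCatch({
        intact <- simulate_kuramoto(theta0, graph, K,
                                    dt_seconds = dt_seconds,
                                    duration_hours = duration_hours)
        dev <- vapply(SLICE_ORIENTATIONS, function(o) {
          sliced <- simulate_kuramoto(theta0[slabs[[o]]], subgraphs[[o]], K,
                                      dt_seconds = dt_seconds,
                                      duration_hours = duration_hours)
          d <- deviation_statistic(intact, sliced, slabs[[o]],
                                   at_hour = duration_hours)
          differences[[sprintf("q%0.3g_K%0.3g_%s", q, K, o)]] <<-
            attr(d, "differences")
          as.numeric(d)
        }, numeric(1))
        win <- if (diff(range(dev)) < 1e-12) "tie" else
          SLICE_ORIENTATIONS[which.max(dev)]
        list(dev = dev, win = win, ok = TRUE)
      }, error = function(e) {
        list(dev = stats::setNames(rep(NA_real_, 3), SLICE_ORIENTATIONS),
             win = NA_character_, ok = FALSE)
      })
      winner[qi, ki] <- cell$win
      results[[length(results) + 1L]] <- data.frame(
        q = q, K = K, orientation = SLICE_ORIENTATIONS,
        deviation_radians = unname(cell$dev),
        deviation_hours = radians_to_hours(unname(cell$dev)),
        winner = cell$win, ok = cell$ok
      )
    }
  }
  structure(list(results = do.call(rbind, results), winner = winner,
                 differences = differences,
                 q_grid = q_grid, K_grid = K_grid, seed = seed),
            class = "scn_sweep")
}

#' @export
print.scn_sweep <- function(x, ...) {
  cat(sprintf("<scn_sweep> %d x %d (q, K) grid; winners:\n",
              length(x$q_grid), length(x$K_grid)))
  print(x$winner)
  invisible(x)
}
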