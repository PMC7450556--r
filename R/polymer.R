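#' Restraint set for polymer optimization
#'
#' Two classes of harmonic bias potentials shape each conformation:
#' chromatin connectivity (sequential beads of a chain held at
#' `bond_length`) and chromatin activity (each bead held at a target radius
#' from the nuclear center derived from its compartment degree).
#'
#' @param radial_targets per-bead target distance to the nuclear center, in
#'   model units; see [assign_radial_targets()].
#' @param bond_length target distance between sequential beads (model
#'   units).
#' @param bond_k,radial_k harmonic weights (> 0). The radial biases carry
#'   the compartment information, so they default to five times the bond
#'   weight; connectivity acts as a soft regularizer.
#' @param confinement_radius nuclear radius R; all targets must lie in
#'   (0, R].
#' @return object of class `restraint_set`.
#' @export
restraint_set <- function(radial_targets, bond_length = 1.0, bond_k = 1.0,
                          radial_k = 5.0, confinement_radius = 10.0) {
  radial_targets <- as.numeric(radial_targets)
  if (any(!is.finite(radial_targets)) ||
      any(radial_targets <= 0 | radial_targets > confinement_radius))
    stop("radial targets must lie in (0, confinement_radius]")
  if (bond_length <= 0 || bond_k <= 0 || radial_k <= 0)
    stop("bond_length and restraint weights must be positive")
  structure(list(bond_length = bond_length, bond_k = bond_k,
                 radial_targets = radial_targets, radial_k = radial_k,
                 confinement_radius = confinement_radius),
            class = "restraint_set")
}

#' Map compartment degree to radial targets
#'
#' Active (high-degree, A-compartment) chromatin sits nearer the nuclear
#' center. Targets are linear in the within-genome rank of the degree: the
#' bead with maximal degree gets `r_min`, the minimal one `r_max`; ties get
#' averaged ranks. A constant profile yields all-`(r_min+r_max)/2` with a
#' warning.
#'
#' @param degree per-bead compartment degree (full genome).
#' @param r_min,r_max radial range in model units; `r_min < r_max`.
#' @return numeric vector of per-bead radial targets.
#' @export
assign_radial_targets <- function(degree, r_min = 2.0, r_max = 9.5) {
  if (!(r_min < r_max) || r_min <= 0)
    stop("need 0 < r_min < r_max")
  degree <- as.numeric(degree)
  if (anyNA(degree)) stop("degree contains NA; interpolate masked bins first")
  n <- length(degree)
  if (n == 1L || diff(range(degree)) == 0) {
    warning("constant compartment profile; all radial targets set to midpoint")
    return(rep((r_min + r_max) / 2, n))
  }
  rk <- rank(degree, ties.method = "average") # 1 = smallest degree
  u <- (rk - 1) / (n - 1)
  r_max - u * (r_max - r_min)
}

chain_starts <- function(bins) {
  as.integer(bins$bin_offsets + 1L)
}

bond_pairs <- function(bins) {
  # sequential bead pairs, never spanning a chromosome (chain) break
  starts <- chain_starts(bins)
  i <- seq_len(bins$n_bins - 1L)
  keep <- !((i + 1L) %in% starts)
  cbind(i[keep], i[keep] + 1L)
}

#' Random initial conformation
#'
#' Each chromosome chain is laid down as a random walk with step length
#' equal to `bond_length`, confined to the nuclear sphere of radius R
#' (steps leaving the sphere are re-drawn). Identical seeds give identical
#' coordinates.
#'
#' @param bins a [bin_table()]; one chain per chromosome.
#' @param restraints a [restraint_set()] with one radial target per bead.
#' @param seed integer RNG seed.
#' @return object of class `conformation`: `coords` (n x 3 matrix),
#'   `chain_breaks` (bead indices starting a new chain), `energy`, `seed`.
#' @export
initialize_random_conformation <- function(bins, restraints, seed = 1L) {
  stopifnot(inherits(bins, "bin_table"), inherits(restraints, "restraint_set"))
  if (length(restraints$radial_targets) != bins$n_bins)
    stop("restraints cover ", length(restraints$radial_targets),
         " beads but the genome has ", bins$n_bins, " bins")
  R <- restraints$confinement_radius
  b <- restraints$bond_length
  coords <- withr::with_seed(as.integer(seed), {
    xyz <- matrix(0, bins$n_bins, 3L)
    starts <- chain_starts(bins)
    for (ci in seq_along(starts)) {
      from <- starts[ci]
      to <- if (ci < length(starts)) starts[ci + 1L] - 1L else bins$n_bins
      # chain origin: uniform in the half-radius ball, leaving room to walk
      repeat {
        p <- stats::runif(3L, -R / 2, R / 2)
        if (sum(p^2) <= (R / 2)^2) break
      }
      xyz[from, ] <- p
      if (to > from) {
        for (i in (from + 1L):to) {
          repeat {
            step <- stats::rnorm(3L)
            step <- step / sqrt(sum(step^2)) * b
            q <- xyz[i - 1L, ] + step
            if (sum(q^2) <= R^2) break
          }
          xyz[i, ] <- q
        }
      }
    }
    xyz
  })
  conf <- structure(list(coords = coords, chain_breaks = chain_starts(bins),
                         energy = NA_real_, seed = as.integer(seed),
                         bins = bins),
                    class = "conformation")
  conf$energy <- conformation_energy(conf, restraints)
  conf
}

#' Bias-potential energy of a conformation
#'
#' `E = bond_k * sum_bonds (d - bond_length)^2 +
#'  radial_k * sum_beads (|r| - target)^2`. Non-negative; zero exactly when
#' every restraint is satisfied.
#'
#' @param conf a `conformation`.
#' @param restraints a [restraint_set()].
#' @return scalar energy.
#' @export
conformation_energy <- function(conf, restraints) {
  x <- conf$coords
  bp <- bond_pairs(conf$bins)
  dvec <- x[bp[, 1L], , drop = FALSE] - x[bp[, 2L], , drop = FALSE]
  d <- sqrt(rowSums(dvec^2))
  r <- sqrt(rowSums(x^2))
  restraints$bond_k * sum((d - restraints$bond_length)^2) +
    restraints$radial_k * sum((r - restraints$radial_targets)^2)
}

#' Optimize a conformation under its restraints
#'
#' Gradient descent on the bias-potential energy with an adaptive step
#' (backtracking halves the step on any energy increase, so the energy is
#' non-increasing by construction). Terminates at the iteration budget or
#' when the relative energy improvement drops below `tol`.
#'
#' @param conf initial `conformation` (e.g. from
#'   [initialize_random_conformation()]).
#' @param restraints a [restraint_set()].
#' @param max_iter iteration budget.
#' @param tol relative energy-change tolerance.
#' @param step0 initial step size in model units.
#' @return optimized `conformation` with its final `energy`; the initial
#'   seed is carried through.
#' @export
optimize_conformation <- function(conf, restraints, max_iter = 5000L,
                                  tol = 1e-6, step0 = 0.05) {
  stopifnot(inherits(conf, "conformation"), inherits(restraints, "restraint_set"))
  if (nrow(conf$coords) != length(restraints$radial_targets))
    stop("conformation and restraints disagree on bead count")
  x <- conf$coords
  bp <- bond_pairs(conf$bins)
  e <- conformation_energy(conf, restraints)
  if (!is.finite(e)) stop("non-finite energy at iteration 0")
  step <- step0
  for (it in seq_len(max_iter)) {
    if (e == 0) break
    g <- polymer_grad(x, bp, restraints)
    repeat {
      xn <- x - step * g
      cn <- conf; cn$coords <- xn
      en <- conformation_energy(cn, restraints)
      if (!is.finite(en)) stop("non-finite energy at iteration ", it)
      if (en <= e) break
      step <- step / 2
      if (step < 1e-14) break
    }
    if (en > e) break # step underflow: converged to numerical precision
    rel <- (e - en) / max(e, .Machine$double.eps)
    x <- xn
    e <- en
    step <- min(step * 1.25, 1.0)
    if (rel < tol) break
  }
  conf$coords <- x
  conf$energy <- e
  conf
}

# analytic gradient of the bias potential (bond + radial terms)
polymer_grad <- function(x, bp, restraints) {
  g <- matrix(0, nrow(x), 3L)
  dvec <- x[bp[, 1L], , drop = FALSE] - x[bp[, 2L], , drop = FALSE]
  d <- pmax(sqrt(rowSums(dvec^2)), 1e-12)
  gb <- dvec * (2 * restraints$bond_k * (d - restraints$bond_length) / d)
  # sequential bonds: each bead heads and tails at most one bond each
  for (k in 1:3) {
    acc <- numeric(nrow(x))
    acc[bp[, 1L]] <- gb[, k]
    acc[bp[, 2L]] <- acc[bp[, 2L]] - gb[, k]
    g[, k] <- acc
  }
  r <- pmax(sqrt(rowSums(x^2)), 1e-12)
  g + x * (2 * restraints$radial_k * (r - restraints$radial_targets) / r)
}

#' Generate an ensemble of optimized conformations
#'
#' Independent restarts: replica `r` is initialized with seed
#' `base_seed + r` and optimized under the shared restraints. The default
#' of 300 replicas averages out the arbitrariness of individual optimized
#' structures.
#'
#' @param bins a [bin_table()].
#' @param restraints a [restraint_set()].
#' @param n_replicas number of replicas (default 300).
#' @param base_seed integer; replica seeds are `base_seed + 1 .. base_seed +
#'   n_replicas`.
#' @param max_iter,tol,step0 passed to [optimize_conformation()].
#' @return object of class `conformation_ensemble`: `replicas` (list of
#'   conformations), `restraints`, `bins`, `base_seed`.
#' @export
generate_ensemble <- function(bins, restraints, n_replicas = 300L,
                              base_seed = 1L, max_iter = 5000L, tol = 1e-6,
                              step0 = 0.05) {
  if (n_replicas < 1L) stop("n_replicas must be >= 1")
  replicas <- vector("list", n_replicas)
  for (r in seq_len(n_replicas)) {
    init <- initialize_random_conformation(bins, restraints,
                                           seed = base_seed + r)
    replicas[[r]] <- tryCatch(
      optimize_conformation(init, restraints, max_iter = max_iter,
                            tol = tol, step0 = step0),
      error = function(e) stop("replica with seed ", base_seed + r,
                               " failed: ", conditionMessage(e)))
  }
  structure(list(replicas = replicas, restraints = restraints, bins = bins,
                 base_seed = as.integer(base_seed)),
            class = "conformation_ensemble")
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  e <- vapply(x$replicas, `[[`, numeric(1), "energy")
  cat(sprintf("conformation_ensemble: %d replicas x %d beads, energy %.3g-%.3g\n",
              length(x$replicas), x$bins$n_bins, min(e), max(e)))
  invisible(x)
}

#' Mean bead radius across an ensemble
#'
#' @param ensemble a `conformation_ensemble`.
#' @return numeric vector, one mean radial distance per bead.
#' @export
mean_bead_radius <- function(ensemble) {
  rs <- vapply(ensemble$replicas,
               function(cf) sqrt(rowSums(cf$coords^2)),
               numeric(ensemble$bins$n_bins))
  rowMeans(rs)
}

#' Write an ensemble as XYZ files plus a JSON sidecar
#'
#' One whitespace-delimited file per replica (`replica_<r>.xyz`: bead id, x,
#' y, z) and `ensemble.json` recording restraint parameters and seeds.
#'
#' @param ensemble a `conformation_ensemble`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_along(ensemble$replicas)) {
    cf <- ensemble$replicas[[r]]
    df <- data.frame(bead = seq_len(nrow(cf$coords)) - 1L,
                     x = cf$coords[, 1L], y = cf$coords[, 2L],
                     z = cf$coords[, 3L])
    utils::write.table(df, file.path(dir, sprintf("replica_%03d.xyz", r)),
                       sep = " ", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  meta <- list(
    n_replicas = length(ensemble$replicas),
    base_seed = ensemble$base_seed,
    seeds = vapply(ensemble$replicas, `[[`, integer(1), "seed"),
    energies = vapply(ensemble$replicas, `[[`, numeric(1), "energy"),
    restraints = ensemble$restraints[c("bond_length", "bond_k", "radial_k",
                                       "confinement_radius")],
    radial_targets = ensemble$restraints$radial_targets,
    chrom_names = ensemble$bins$chrom_names,
    chrom_lengths = as.numeric(ensemble$bins$chrom_lengths),
    bin_size = ensemble$bins$bin_size)
  jsonlite::write_json(meta, file.path(dir, "ensemble.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an ensemble written by [write_ensemble()]
#'
#' @param dir directory containing `replica_*.xyz` and `ensemble.json`.
#' @return a `conformation_ensemble`.
#' @export
read_ensemble <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "ensemble.json"),
                              simplifyVector = TRUE)
  sizes <- meta$chrom_lengths
  names(sizes) <- meta$chrom_names
  bins <- bin_table(sizes, bin_size = meta$bin_size)
  restraints <- restraint_set(meta$radial_targets,
                              bond_length = meta$restraints$bond_length,
                              bond_k = meta$restraints$bond_k,
                              radial_k = meta$restraints$radial_k,
                              confinement_radius = meta$restraints$confinement_radius)
  files <- sort(list.files(dir, pattern = "^replica_\\d+\\.xyz$",
                           full.names = TRUE))
  replicas <- lapply(seq_along(files), function(r) {
    df <- utils::read.table(files[r], header = FALSE,
                            col.names = c("bead", "x", "y", "z"))
    cf <- structure(list(coords = as.matrix(df[, c("x", "y", "z")]),
                         chain_breaks = chain_starts(bins),
                         energy = meta$energies[r], seed = meta$seeds[r],
                         bins = bins),
                    class = "conformation")
    dimnames(cf$coords) <- NULL
    cf
  })
  structure(list(replicas = replicas, restraints = restraints, bins = bins,
                 base_seed = meta$base_seed),
            class = "conformation_ensemble")
}
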