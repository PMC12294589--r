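# Configuration, orchestration and file I/O tying the modules into
# reproducible runs.  Configurations are YAML (diff-able and
# language-neutral); outputs are TSV with a commented header carrying the
# config hash and seed, plus a JSON manifest.

.rc_allowed <- list(
  top = c("system", "potential", "method", "sampling", "propagation",
          "observables", "output_dir", "seed"),
  system = c("beta", "masses", "hbar"),
  potential = c("name", "params"),
  sampling = c("n_centroids", "n_planets", "burn_in", "thin", "step"),
  propagation = c("dt", "nsteps")
)

.check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop(sprintf("unknown config key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
}

#' Validate (and normalize) a run configuration
#'
#' A run configuration fully specifies a reproducible computation: the
#' thermal system, the potential, the method
#' (\code{fklpi_standard}, \code{fklpi_planetary}, \code{classical},
#' \code{fk_cmd}), sampling and propagation settings, the observables and a
#' mandatory seed.  Unknown keys are rejected.
#'
#' @param config Named list (e.g. from \code{\link{read_run_config}}).
#' @return The validated config (class \code{"fklpi_config"}).
#' @export
validate_run_config <- function(config) {
  .check_keys(config, .rc_allowed$top, "top level")
  for (sec in c("system", "potential", "sampling", "propagation")) {
    if (is.null(config[[sec]])) {
      stop(sprintf("config section '%s' is required", sec), call. = FALSE)
    }
  }
  .check_keys(config$system, .rc_allowed$system, "system")
  .check_keys(config$potential, .rc_allowed$potential, "potential")
  .check_keys(config$sampling, .rc_allowed$sampling, "sampling")
  .check_keys(config$propagation, .rc_allowed$propagation, "propagation")
  if (is.null(config$seed)) stop("config requires a seed", call. = FALSE)
  config$method <- match.arg(config$method %||% "fklpi_standard",
                             c("fklpi_standard", "fklpi_planetary",
                               "classical", "fk_cmd"))
  config$observables <- config$observables %||% "position_cf"
  ok_obs <- c("position_cf", "momentum_cf", "velocity_cf")
  bad <- setdiff(unlist(config$observables), ok_obs)
  if (length(bad)) {
    stop(sprintf("unknown observable(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  stopifnot_scalar(config$system$beta, "system.beta", positive = TRUE)
  stopifnot_scalar(config$propagation$dt, "propagation.dt", positive = TRUE)
  structure(config, class = "fklpi_config")
}

#' Read a YAML run configuration
#'
#' @param path Path to the YAML file.
#' @return Validated config.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Serialize a run configuration to YAML
#'
#' \code{parse(serialize(x))} is the identity on validated configs.
#'
#' @param config Validated config.
#' @param path Optional output path; when omitted the YAML text is
#'   returned.
#' @export
write_run_config <- function(config, path = NULL) {
  txt <- yaml::as.yaml(unclass(config))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' MD5 hash of a run configuration
#'
#' Hash of the canonical YAML serialization; stamped into every output file
#' of a run so that mixed bundles can be detected.
#'
#' @param config Validated config.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  x <- unclass(config)
  x$output_dir <- NULL    # where results land does not change what they are
  x <- x[order(names(x))]
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(x), tf)
  unname(tools::md5sum(tf))
}

# TSV with commented key: value header lines.
write_tsv_with_header <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]])), con)
  }
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_tsv_with_header <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^# ", "", lines[h])
    k <- sub(":.*$", "", kv)
    meta[[k]] <- trimws(sub("^[^:]*:", "", kv))
  }
  df <- utils::read.table(text = lines[setdiff(seq_along(lines), hdr)],
                          header = TRUE, sep = "\t")
  attr(df, "meta") <- meta
  df
}

#' Effective-frequency scan over a centroid grid
#'
#' @param model 1D model potential.
#' @param system A \code{\link{thermal_system}}.
#' @param xs Centroid grid.
#' @param ... Options for \code{\link{solve_effective_frequency}}.
#' @return Data frame with columns \code{xc}, \code{omega2}, \code{a2},
#'   \code{alpha}, \code{W1}, \code{iterations}, \code{converged}.
#' @export
freq_scan <- function(model, system, xs, ...) {
  rows <- lapply(xs, function(x) {
    e <- solve_effective_frequency(model, x, system, ...)
    data.frame(xc = e$xc, omega2 = e$omega2, a2 = e$a2, alpha = e$alpha,
               W1 = e$W1, iterations = e$iterations,
               converged = e$converged)
  })
  do.call(rbind, rows)
}

#' Write a correlation series as TSV
#'
#' Columns \code{t}, \code{re}, \code{im}, \code{stderr}; header lines
#' carry the metadata passed in \code{meta}.
#'
#' @param cf A \code{\link{correlation_series}}.
#' @param path Output path.
#' @param meta Named list of header metadata (config hash, seed, ...).
#' @export
write_cf_tsv <- function(cf, path, meta = list()) {
  df <- data.frame(t = cf$times, re = Re(cf$values), im = Im(cf$values),
                   stderr = cf$stderr %||% NA_real_)
  meta$kind <- cf$kind
  meta$n_samples <- cf$n_samples
  write_tsv_with_header(df, path, meta)
}

#' Write / read 1D liquid configurations as XYZ
#'
#' One frame: count line, comment line carrying \code{box = L}, then one
#' \code{element x y z} line per particle (y = z = 0 for the 1D liquids).
#'
#' @param coords Numeric vector of particle positions.
#' @param path File path.
#' @param box Box length (stored on the comment line).
#' @param element Element label (default \code{"Ar"}).
#' @export
write_xyz <- function(coords, path, box, element = "Ar") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(length(coords)), sprintf("box = %.12g", box)),
             con)
  writeLines(sprintf("%s %.12g 0 0", element, coords), con)
  invisible(path)
}

#' @rdname write_xyz
#' @return \code{read_xyz}: list with \code{coords}, \code{box}.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  box <- as.numeric(sub(".*box *= *", "", lines[2]))
  coords <- vapply(strsplit(trimws(lines[3:(2 + n)]), "\\s+"),
                   function(f) as.numeric(f[2]), numeric(1))
  list(coords = coords, box = box)
}

#' Persist / restore a sampled ensemble
#'
#' Stores centroids, seeds and the config hash for reuse across
#' propagation runs.
#'
#' @param ensemble A \code{\link{sample_centroid_ensemble}} result.
#' @param path Archive path (RDS).
#' @param hash Config hash recorded with the archive.
#' @export
save_ensemble <- function(ensemble, path, hash = NA_character_) {
  saveRDS(list(ensemble = ensemble, hash = hash,
               version = as.character(utils::packageVersion("fklpi"))),
          path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  readRDS(path)
}

#' Run a configured computation
#'
#' Orchestrates a full run: sample the centroid ensemble (or, for
#' \code{method = "classical"}, a classical Boltzmann ensemble), propagate,
#' assemble the requested correlation functions, and write one TSV per
#' observable plus a JSON manifest into \code{output_dir}.  Deterministic
#' given the seed; all outputs carry the config hash.
#'
#' @param config Validated \code{\link{validate_run_config}} result (or a
#'   plain list, validated on entry).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the computed series, output paths and the
#'   manifest.
#' @export
run <- function(config, quiet = FALSE) {
  config <- validate_run_config(unclass(config))
  hash <- config_hash(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sys <- thermal_system(config$system$beta,
                        config$system$masses %||% 1,
                        config$system$hbar %||% 1)
  model <- make_model_potential(config$potential$name,
                                config$potential$params %||% list())
  sp <- config$sampling; pr <- config$propagation
  seed <- as.integer(config$seed)
  n_c <- sp$n_centroids %||% 500L
  obs_kind <- sub("_cf$", "", unlist(config$observables))
  results <- list(); paths <- character(0)
  if (config$method == "classical") {
    say("stage sample: classical Boltzmann Metropolis (n = %d)", n_c)
    ens <- .classical_ensemble(model, sys, n_c, seed,
                               burn_in = sp$burn_in %||% 500L,
                               thin = sp$thin %||% 5L)
    for (ob in obs_kind) {
      cf <- .classical_cf(model, sys, ens, ob, pr$dt, pr$nsteps)
      results[[paste0(ob, "_cf")]] <- cf
    }
    acc <- attr(ens, "acceptance")
    conv_stats <- list()
  } else {
    say("stage sample: FK centroid Metropolis (n = %d)", n_c)
    ens <- tryCatch(
      sample_centroid_ensemble(model, sys, n_c, seed = seed,
                               burn_in = sp$burn_in %||% 500L,
                               thin = sp$thin %||% 5L,
                               step = sp$step),
      error = function(e) stop("stage sample failed: ", conditionMessage(e),
                               call. = FALSE))
    acc <- ens$acceptance
    iters <- vapply(ens$eff, `[[`, integer(1), "iterations")
    conv_stats <- list(mean_iterations = mean(iters),
                       max_iterations = max(iters),
                       eff_failures = ens$n_eff_failures)
    propagator <- switch(config$method,
                         fklpi_standard = "classical",
                         fklpi_planetary = "planetary",
                         fk_cmd = "fk_cmd")
    flavor <- if (config$method == "fk_cmd") "kubo" else "standard"
    for (ob in obs_kind) {
      say("stage correlate: %s (%s, %s)", ob, propagator, flavor)
      cf <- tryCatch(
        correlation_function(model, sys, ens, A = ob, B = ob,
                             flavor = flavor, propagator = propagator,
                             n_planets = sp$n_planets %||% 10L,
                             dt = pr$dt, nsteps = pr$nsteps,
                             seed = seed + 1L),
        error = function(e) stop("stage correlate failed: ",
                                 conditionMessage(e), call. = FALSE))
      results[[paste0(ob, "_cf")]] <- cf
    }
  }
  meta <- list(config_hash = hash, seed = seed,
               package = as.character(utils::packageVersion("fklpi")))
  for (nm in names(results)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_cf_tsv(results[[nm]], p, meta)
    paths <- c(paths, p)
  }
  manifest <- c(meta, list(method = config$method,
                           acceptance = acc,
                           convergence = conv_stats,
                           outputs = basename(paths)))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  say("run complete: %d output file(s) in %s", length(paths), out_dir)
  invisible(list(results = results, paths = c(paths, mp),
                 manifest = manifest, hash = hash))
}

# Classical Boltzmann sampling and correlation (reference method for QCF
# ratios): Metropolis in q on exp(-beta V), exact Maxwell momenta.
.classical_ensemble <- function(model, system, n, seed, burn_in = 500L,
                                thin = 5L) {
  set.seed(seed)
  mass <- system$masses[1]
  step <- 1 / sqrt(system$beta * mass)
  x <- 0; vx <- value_1d(model, x)
  n_acc <- 0L; n_prop <- 0L
  xs <- numeric(n)
  kept <- 0L; sweep <- 0L
  while (kept < n) {
    sweep <- sweep + 1L
    xp <- x + stats::rnorm(1L, 0, step)
    vp <- value_1d(model, xp)
    if (log(stats::runif(1L)) < -system$beta * (vp - vx)) {
      x <- xp; vx <- vp
      if (sweep > burn_in) n_acc <- n_acc + 1L
    }
    if (sweep > burn_in) n_prop <- n_prop + 1L
    if (sweep <= burn_in && sweep %% 50L == 0L) {
      # crude tune toward ~40% using recent acceptance is omitted; the
      # thermal-width step works well for the built-in models
    }
    if (sweep > burn_in && (sweep - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      xs[kept] <- x
    }
  }
  p <- stats::rnorm(n, 0, sqrt(mass / system$beta))
  structure(list(q = xs, p = p), acceptance = n_acc / n_prop)
}

.classical_cf <- function(model, system, ens, kind, dt, nsteps) {
  mass <- system$masses[1]
  A0 <- .b_symbol(kind, ens$q, ens$p, mass)
  acc <- matrix(0, nsteps + 1L, 1L)
  record <- function(k, q, p) {
    acc[k + 1L, 1L] <<- mean(A0 * .b_symbol(kind, q, p, mass))
  }
  verlet_ensemble_1d(function(x) gradient_1d(model, x),
                     ens$q, ens$p, mass, dt, nsteps, record)
  correlation_series(dt * (0:nsteps), as.complex(acc[, 1L]),
                     kind = "standard", n_samples = length(ens$q))
}

#' Standard test fixtures
#'
#' Regenerates (deterministically from the seed) the fixture set used
#' throughout the test suite: harmonic systems at three temperatures, the
#' quartic oscillator, the low-temperature double well, a parabolic barrier
#' just inside the momentum-sampling validity bound, and a 16-particle 1D
#' pair liquid.
#'
#' @param seed Integer seed.
#' @return Named list of fixtures; each entry carries \code{model},
#'   \code{system} and (where cheap) sampled data.
#' @export
fixture_ensembles <- function(seed = 1L) {
  out <- list()
  for (beta in c(0.1, 1, 8)) {
    sys <- thermal_system(beta)
    model <- make_model_potential("harmonic", list(M = 1, omega = 1))
    ens <- sample_centroid_ensemble(model, sys, 200L, seed = seed,
                                    burn_in = 200L, thin = 2L)
    out[[sprintf("harmonic_beta%g", beta)]] <-
      list(model = model, system = sys, centroids = ens)
  }
  sys_q <- thermal_system(1)
  model_q <- make_model_potential("quartic", list(c = 1))
  out$quartic <- list(
    model = model_q, system = sys_q,
    centroids = sample_centroid_ensemble(model_q, sys_q, 200L, seed = seed,
                                         burn_in = 200L, thin = 2L))
  sys_dw <- thermal_system(8)
  model_dw <- make_model_potential("double_well", list(a = 1, b = 1))
  field_dw <- centroid_field(model_dw, sys_dw, c(-2.5, 2.5), n_grid = 101L)
  out$double_well <- list(
    model = model_dw, system = sys_dw, field = field_dw,
    centroids = sample_centroid_ensemble(model_dw, sys_dw, 200L,
                                         seed = seed, burn_in = 200L,
                                         thin = 2L, field = field_dw))
  # parabolic barrier with hbar*|Omega|*beta = 0.9*pi (inside the bound)
  sys_b <- thermal_system(1)
  model_b <- make_model_potential("parabolic_barrier",
                                  list(M = 1, omega_b = 0.9 * pi))
  eff_b <- solve_effective_frequency(model_b, 0, sys_b)
  out$barrier <- list(
    model = model_b, system = sys_b, eff = eff_b,
    phase_points = sample_barrier_marginal(
      list(xc = 0, pc = 0, eff = eff_b), sys_b, 500L, seed = seed))
  # 16-particle 1D pair liquid on a jittered lattice
  set.seed(seed)
  N <- 16L; L <- N * 2^(1 / 6)
  out$pair_liquid <- list(
    model = make_model_potential("pair_liquid", list(
      n_particles = N, box_length = L,
      pair = list(type = "lennard_jones", epsilon = 1, sigma = 1))),
    system = thermal_system(1, masses = rep(1, N)),
    coords = (seq_len(N) - 0.5) * L / N +
      stats::rnorm(N, 0, 0.02))
  out
}
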