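#' Write trajectories and a manifest to a directory
#'
#' One tab-separated file per trajectory with header `time_s<TAB>A[<TAB>B]`
#' and one row per frame, plus a JSON `manifest.json` recording circuit,
#' rates, frame interval, seed and the file list.
#'
#' @param trajectories list of [FrameSeries-class].
#' @param dir output directory (created if missing).
#' @param circuit,params,seed metadata recorded in the manifest.
#' @return invisibly, the manifest as a list.
#' @export
writeTrajectories <- function(trajectories, dir, circuit = NA_character_,
                              params = NULL, seed = NA_integer_) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  files <- character(length(trajectories))
  for (i in seq_along(trajectories)) {
    t <- trajectories[[i]]
    files[i] <- sprintf("trajectory_%04d.tsv", i)
    df <- data.frame(time_s = (seq_len(nFrames(t)) - 1) * deltaT(t),
                     counts(t), check.names = FALSE)
    utils::write.table(df, file.path(dir, files[i]), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  manifest <- list(schema = "circuitcaliber-manifest-1",
                   circuit = circuit,
                   rates = as.list(params),
                   delta_t = deltaT(trajectories[[1]]),
                   seed = seed,
                   n_trajectories = length(trajectories),
                   software = as.character(utils::packageVersion("CircuitCaliber")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read trajectories written by [writeTrajectories()]
#'
#' Reads every file listed in the directory's manifest (or, lacking one, all
#' `*.tsv` files with `deltaT` supplied), validating integer non-negative
#' counts, unragged rows and a consistent frame interval; errors name the
#' offending file and line.
#'
#' @param dir directory containing trajectories (and usually
#'   `manifest.json`).
#' @param deltaT frame interval override, required when no manifest exists.
#' @return list of [FrameSeries-class] with attribute `manifest`.
#' @export
readTrajectories <- function(dir, deltaT = NULL) {
  manifestPath <- file.path(dir, "manifest.json")
  manifest <- NULL
  if (file.exists(manifestPath)) {
    manifest <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
    files <- manifest$files
    if (is.null(deltaT)) deltaT <- manifest$delta_t
  } else {
    files <- sort(basename(Sys.glob(file.path(dir, "*.tsv"))))
    if (is.null(deltaT))
      stop("no manifest.json in ", dir, ": supply deltaT explicitly")
  }
  if (!length(files)) stop("no trajectory files found in ", dir)
  out <- vector("list", length(files))
  for (i in seq_along(files)) {
    path <- file.path(dir, files[i])
    if (!file.exists(path)) stop("manifest lists missing file: ", path)
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE)
    cts <- as.matrix(df[, -1, drop = FALSE])
    bad <- which(!is.finite(cts) | cts < 0 | cts != round(cts),
                 arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("%s line %d: count is not a non-negative integer",
                   path, bad[1, 1] + 1L))
    if (nrow(df) >= 2) {
      dts <- diff(df$time_s)
      if (max(abs(dts - deltaT)) > 1e-6)
        stop(sprintf("%s: frame interval differs from deltaT = %g", path,
                     deltaT))
    }
    out[[i]] <- FrameSeries(cts, deltaT)
  }
  attr(out, "manifest") <- manifest
  out
}

#' Deterministic small datasets for tests and examples
#'
#' * `birth_death`: birth-death trajectory (`lambda = 0.05`, `mu = 0.002`,
#'   500 frames at 300 s).
#' * `square_wave`: noiseless alternation between a low and a high level
#'   with a fixed dwell (in frames).
#' * `tiny_sgaa`: short SGAA benchmark set (4 trajectories x 24 h) at the
#'   default rates.
#' * `tiny_ts`: short toggle-switch set (2 trajectories x 24 h).
#'
#' @param kind fixture name.
#' @param seed RNG seed.
#' @param dwell dwell time in frames for `square_wave`.
#' @return list of [FrameSeries-class].
#' @export
makeFixture <- function(kind = c("tiny_sgaa", "tiny_ts", "birth_death",
                                 "square_wave"), seed = 1L, dwell = 50L) {
  kind <- match.arg(kind)
  switch(kind,
    birth_death = simulateSSA(
      birthDeathNetwork(0.05, 0.002),
      SimulationConfig(tEnd = 500 * 300 + 3600, deltaT = 300,
                       nTrajectories = 1L, burnIn = 3600, seed = seed)),
    square_wave = {
      lev <- rep(rep(c(5L, 60L), 6), each = dwell)
      list(FrameSeries(lev, 300))
    },
    tiny_sgaa = simulateSSA(
      buildSGAAGenerator(),
      SimulationConfig(tEnd = 24 * 3600 + 12 * 3600, deltaT = 300,
                       nTrajectories = 4L, burnIn = 12 * 3600, seed = seed)),
    tiny_ts = simulateSSA(
      buildTSGenerator(),
      SimulationConfig(tEnd = 24 * 3600 + 12 * 3600, deltaT = 300,
                       nTrajectories = 2L, burnIn = 12 * 3600, seed = seed)))
}

#' Render a benchmark report as an aligned text table
#'
#' Mirrors the accuracy-table layout: a `True` row first, then one row per
#' fitted model with `mean +/- sd` over replicates, all rates displayed in
#' units of 1e-3 / s.
#'
#' @param report a `BenchmarkReport` from [runBenchmark()].
#' @param file optional path for a JSON twin of the report.
#' @return character vector of table lines (invisibly printed with `cat`).
#' @export
renderReport <- function(report, file = NULL) {
  fmt <- function(x, sd) {
    if (is.null(sd) || is.na(sd)) sprintf("%.2g", 1e3 * x)
    else sprintf("%.2g ± %.2g", 1e3 * x, 1e3 * sd)
  }
  hdr <- sprintf("%-8s %-16s %-16s %-16s", "Method",
                 "peff (1e-3/s)", "peff* (1e-3/s)", "reff (1e-3/s)")
  lines <- c(hdr,
             sprintf("%-8s %-16s %-16s %-16s", "True",
                     fmt(report$true[["peff"]], NA),
                     fmt(report$true[["peffStar"]], NA),
                     fmt(report$true[["reff"]], NA)))
  if (!is.null(report$summary)) {
    for (k in seq_len(nrow(report$summary))) {
      s <- report$summary[k, ]
      lines <- c(lines, sprintf("%-8s %-16s %-16s %-16s",
                                toupper(s$method),
                                fmt(s$peff, s$peff_sd),
                                fmt(s$peffStar, s$peffStar_sd),
                                fmt(s$reff, s$reff_sd)))
    }
  }
  if (!is.null(file)) {
    json <- list(schema = "circuitcaliber-report-1",
                 circuit = report$circuit,
                 true = as.list(report$true),
                 summary = report$summary,
                 nmax = report$nmax,
                 nReplicates = report$nReplicates,
                 failures = report$failures)
    jsonlite::write_json(json, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Read a run configuration (YAML or JSON)
#'
#' Validates against a small schema: known keys only, a `circuit`, optional
#' `rates` overriding the defaults, and simulation fields mirroring
#' [SimulationConfig()].
#'
#' @param path configuration file.
#' @return list with `circuit`, `rates`, `config`
#'   (a [SimulationConfig-class]) and any inference settings (`m`, `nmax`,
#'   `models`, `Mgrid`).
#' @export
readRunConfig <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- c("circuit", "rates", "t_end", "delta_t", "n_trajectories",
             "n_replicates", "burn_in", "seed", "m", "nmax", "models",
             "m_grid")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  circuit <- match.arg(raw$circuit, c("sgaa", "ts"))
  rates <- defaultRates(circuit)
  if (!is.null(raw$rates)) {
    bad <- setdiff(names(raw$rates), names(rates))
    if (length(bad)) stop("unknown rate names: ", paste(bad, collapse = ", "))
    rates[names(raw$rates)] <- unlist(raw$rates)
  }
  cfg <- SimulationConfig(
    tEnd = raw$t_end %||% (60 * 3600),
    deltaT = raw$delta_t %||% 300,
    nTrajectories = raw$n_trajectories %||% 1L,
    nReplicates = raw$n_replicates %||% 1L,
    burnIn = raw$burn_in %||% (12 * 3600),
    seed = raw$seed %||% 1L)
  list(circuit = circuit, rates = rates, config = cfg,
       m = raw$m, nmax = raw$nmax, models = raw$models %||% c("dm", "cgm", "maxcal"),
       Mgrid = if (is.null(raw$m_grid)) 1:40 else
         seq(raw$m_grid[[1]], raw$m_grid[[2]]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
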