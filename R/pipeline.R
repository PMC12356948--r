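# ---- Orchestration: grids, trajectory storage, reduced-scale pipeline ----

#' Standard mutation-rate grid
#'
#' The default grid spans the stable regime, the transition region
#' (0.042, 0.045) and both extremes (0.001 well below, 0.06 above the
#' error threshold).  Strictly increasing; any user-supplied grid
#' replaces it verbatim.
#'
#' @return Numeric vector of mutation rates.
#' @examples
#' standardGrid()
#' @export
standardGrid <- function() {
  c(0.001, 0.005, 0.01, 0.02, 0.03, 0.04, 0.042, 0.045, 0.05, 0.06)
}

#' Write an ensemble to the canonical columnar text format
#'
#' One gzip-compressed TSV with columns \code{run_id}, \code{generation},
#' \code{species_id}, \code{count}, plus a JSON sidecar
#' (\code{<path>.meta.json}) recording every model parameter and derived
#' seed.
#'
#' @param ens a \linkS4class{TanaEnsemble}.
#' @param path output file path (conventionally ending in
#'   \code{.tsv.gz}).
#' @return \code{path}, invisibly.
#' @export
writeTrajectories <- function(ens, path) {
  tabs <- lapply(seq_along(ens@members), function(r) {
    rec <- ens@members[[r]]@records
    data.frame(run_id = r, generation = rec$generation,
               species_id = rec$speciesId, count = rec$count)
  })
  tab <- do.call(rbind, tabs)
  con <- gzfile(path, "w")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p <- ens@members[[1]]@params
  meta <- list(
    L = p@L, theta = p@theta, pKill = p@pKill, pMut = p@pMut, k = p@k,
    mu = p@mu, n0 = p@n0, n0Species = p@n0Species,
    masterSeed = ens@masterSeed, sharedJ = ens@sharedJ,
    horizon = ens@horizon,
    runSeeds = vapply(ens@members, function(m) m@params@seed, numeric(1)),
    seedRun = vapply(ens@members, function(m) m@seedRun, numeric(1)),
    seedJ = vapply(ens@members, function(m) m@seedJ, numeric(1)),
    terminatedEarly = vapply(ens@members, function(m) m@terminatedEarly,
                             logical(1)),
    neutral = ens@members[[1]]@neutral)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ensemble from the canonical columnar text format
#'
#' @param path file written by \code{\link{writeTrajectories}}.
#' @return A \linkS4class{TanaEnsemble}.
#' @export
readTrajectories <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  tab <- utils::read.table(gzfile(path), header = TRUE, sep = "\t")
  members <- lapply(sort(unique(tab$run_id)), function(r) {
    sub <- tab[tab$run_id == r, ]
    p <- tanaParams(pMut = meta$pMut, L = meta$L, theta = meta$theta,
                    pKill = meta$pKill, k = meta$k, mu = meta$mu,
                    n0 = meta$n0, n0Species = meta$n0Species,
                    seed = meta$runSeeds[r])
    totals <- as.integer(tapply(sub$count, sub$generation, sum))
    new("TanaTrajectory", params = p,
        records = data.frame(generation = sub$generation,
                             speciesId = sub$species_id,
                             count = sub$count),
        totals = totals,
        terminatedEarly = meta$terminatedEarly[r],
        seedRun = meta$seedRun[r], seedJ = meta$seedJ[r],
        neutral = meta$neutral)
  })
  new("TanaEnsemble", members = members,
      horizon = as.integer(meta$horizon),
      masterSeed = meta$masterSeed, sharedJ = meta$sharedJ)
}

#' Run the full reduced-scale analysis pipeline
#'
#' Simulates an ensemble per mutation rate and runs the three analysis
#' stages — population statistics, individuality scale sweep, and
#' species-environment information profile — writing tidy long-format
#' CSVs and a JSON manifest (all parameters, derived seeds, per-stage
#' timing) to \code{outDir}.  Stages whose output file already exists
#' are skipped, so a partially complete bundle is resumable; a failed
#' stage is recorded in the manifest and downstream work that needs it
#' is skipped with a reason.
#'
#' @param config list with entries \code{pMutGrid} (default
#'   \code{standardGrid()}), \code{nRuns}, \code{nGenerations},
#'   \code{masterSeed}, \code{nRanks}, \code{Krange}, \code{subsetLimit},
#'   \code{stride}, \code{scales}, \code{params} (base
#'   \linkS4class{TanaParams}), and logical stage switches
#'   \code{doPopstats}, \code{doIndividuality}, \code{doInfodyn}.
#' @param outDir output directory (created if absent).
#' @return List with the stage tables and the manifest, invisibly.
#' @export
runPipeline <- function(config = list(), outDir) {
  cfg <- utils::modifyList(list(
    pMutGrid = standardGrid(), nRuns = 100L, nGenerations = 20000L,
    masterSeed = 1, nRanks = 15L, Krange = 1:15, subsetLimit = 100L,
    stride = 5L, scales = c(1L, 6L), params = tanaParams(),
    neutral = FALSE,
    doPopstats = TRUE, doIndividuality = TRUE, doInfodyn = TRUE),
    config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg[setdiff(names(cfg), "params")],
                   params = list(L = cfg$params@L, theta = cfg$params@theta,
                                 pKill = cfg$params@pKill, k = cfg$params@k,
                                 mu = cfg$params@mu, n0 = cfg$params@n0,
                                 n0Species = cfg$params@n0Species),
                   stages = list())
  out <- list()

  stage <- function(name, file, fun) {
    path <- file.path(outDir, file)
    if (file.exists(path)) {
      message("stage '", name, "': output exists, skipping")
      manifest$stages[[name]] <<- list(status = "cached", file = file)
      return(utils::read.csv(path))
    }
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      message("stage '", name, "' failed: ", conditionMessage(res))
      return(NULL)
    }
    utils::write.csv(res, path, row.names = FALSE)
    manifest$stages[[name]] <<- list(
      status = "done", file = file,
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  if (isTRUE(cfg$doPopstats)) {
    out$popstats <- stage("popstats", "popstats.csv", function() {
      sweepPopstats(cfg$pMutGrid, cfg$nRuns, cfg$nGenerations,
                    masterSeed = cfg$masterSeed, params = cfg$params,
                    neutral = cfg$neutral)
    })
  }

  needEns <- isTRUE(cfg$doIndividuality) || isTRUE(cfg$doInfodyn)
  if (needEns) {
    indiv <- list(); info <- list()
    for (gi in seq_along(cfg$pMutGrid)) {
      pm <- cfg$pMutGrid[gi]
      p <- cfg$params
      p@pMut <- pm
      ens <- tanaEnsemble(p, cfg$nRuns, cfg$nGenerations,
                          masterSeed = deriveSeed(cfg$masterSeed,
                                                  7000L + gi),
                          neutral = cfg$neutral)
      ra <- tryCatch(rankAlign(ens, nRanks = cfg$nRanks),
                     error = function(e) e)
      if (inherits(ra, "error")) {
        manifest$stages[[paste0("align_", pm)]] <-
          list(status = "failed", error = conditionMessage(ra))
        next
      }
      if (isTRUE(cfg$doIndividuality)) {
        sw <- scaleSweep(ra, Krange = cfg$Krange,
                         subsetLimit = cfg$subsetLimit,
                         stride = cfg$stride)
        indiv[[gi]] <- cbind(pMut = pm, sw$table,
                             optimalScale = sw$optimalScale)
      }
      if (isTRUE(cfg$doInfodyn)) {
        info[[gi]] <- do.call(rbind, lapply(cfg$scales, function(s)
          cbind(pMut = pm,
                speciesEnvironmentProfile(ra, scale = s,
                                          stride = cfg$stride))))
      }
    }
    if (isTRUE(cfg$doIndividuality) && length(indiv)) {
      out$individuality <- do.call(rbind, indiv)
      utils::write.csv(out$individuality,
                       file.path(outDir, "individuality.csv"),
                       row.names = FALSE)
      manifest$stages$individuality <- list(status = "done",
                                            file = "individuality.csv")
    }
    if (isTRUE(cfg$doInfodyn) && length(info)) {
      out$infodyn <- do.call(rbind, info)
      utils::write.csv(out$infodyn, file.path(outDir, "infodyn.csv"),
                       row.names = FALSE)
      manifest$stages$infodyn <- list(status = "done",
                                      file = "infodyn.csv")
    }
  }

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(out, list(manifest = manifest)))
}
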