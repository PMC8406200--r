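#' @include synthetic.R interfaces.R
NULL

#' Default analysis configuration
#'
#' Parameters of the full tetramer-vs-octamer comparison. Cutoffs follow the
#' production analysis (7.5 Angstrom native contacts and junction
#' interfaces, 6 Angstrom pocket expansion); the DMD block defaults to a
#' scaled-down protocol (8 replicas x 2e5 steps with the first third
#' discarded) whose full production scale (39 replicas x 6e6 steps, last
#' two thirds analyzed) is reachable via \code{paperScale = TRUE}.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param paperScale use the full production replica count and step count.
#' @return a nested configuration list.
#' @export
analysisConfig <- function(seed = 1, paperScale = FALSE) {
  list(
    seed = seed,
    synth = list(nRes = 40L, expansion = 6.0),
    contacts = list(cutoff = 7.5, minSeqSep = 2L),
    interfaceCutoff = 7.5,
    gnm = list(cutoff = 7.5, modes = 12L, lowModes = 5L,
               minParticipation = 0.05),
    dmd = list(replicas = if (paperScale) 39L else 8L,
               nSteps = if (paperScale) 6e6 else 2e5,
               temperature = 0.5, snapshotEvery = 1000L,
               thermostatRate = 1, burnInFraction = 1 / 3),
    sasa = list(probe = 1.4, nPoints = 960L),
    filament = list(twist = 40, rise = 50, kink = 30, nCopies = 9L)
  )
}

.pocketIndexList <- function(ca, pockets) {
  lapply(pockets, function(p) beadIndices(ca, p))
}

#' Run the full filamentation analysis end-to-end
#'
#' Orchestrates the pipeline on the synthetic planted-effect pair: fixture
#' generation, selections (pockets, junction interfaces), GNM correlation
#' profiles of the free tetramer and the linked octamer, replicated DMD with
#' pooled pocket d_rms for both systems, buried-interface areas at the
#' junction, and filament reconstruction with screw/kink recovery. All
#' randomness derives from \code{config$seed}, so a fixed configuration
#' yields an identical report.
#'
#' @param config list from [analysisConfig()].
#' @param stages character vector of stages to run (subset of
#'   \code{c("gnm", "dmd", "interface", "filament")}; selections always
#'   run).
#' @param verbose print stage progress (default FALSE).
#' @return a nested report list; see the vignette for the layout.
#' @export
runAnalysis <- function(config = analysisConfig(),
                        stages = c("gnm", "dmd", "interface", "filament"),
                        verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  report <- list(config = config)

  say("generating synthetic systems")
  tet <- makeTetramerAnalog(config$synth$nRes, seed = config$seed,
                            expansion = config$synth$expansion)
  oct <- makeOctamerAnalog(config$synth$nRes, seed = config$seed,
                           expansion = config$synth$expansion)

  caT <- extractCA(tet$structure)
  caO <- extractCA(oct$structure)
  pockT <- .pocketIndexList(caT, tet$pockets)
  pockO <- .pocketIndexList(caO, oct$pockets)

  say("selections")
  junT <- junctionResidues(oct$structure, oct$tetramer1, oct$linkers,
                           oct$tetramer2, config$interfaceCutoff)
  report$selections <- list(
    pocketSizes = vapply(pockT, length, integer(1)),
    junctionSize = length(junT),
    nativeContactsTetramer = length(nativeContacts(
      caT, config$contacts$cutoff, config$contacts$minSeqSep)),
    nativeContactsOctamer = length(nativeContacts(
      caO, config$contacts$cutoff, config$contacts$minSeqSep)))

  if ("gnm" %in% stages) {
    say("GNM normal modes")
    spT <- gnmModes(caT, config$gnm$cutoff)
    spO <- gnmModes(caO, config$gnm$cutoff)
    mp <- config$gnm$minParticipation
    profT <- pooledCorrelationProfile(spT, pockT, config$gnm$modes,
                                      minParticipation = mp)
    profO <- pooledCorrelationProfile(spO, pockO, config$gnm$modes,
                                      minParticipation = mp)
    junIdx <- beadIndices(caO, junT)
    # the same residues on the isolated tetramer are the reference state
    junTetIdx <- beadIndices(caT, residueSet(
      junT@ids$chain[junT@ids$chain %in% oct$tetramer1],
      junT@ids$resno[junT@ids$chain %in% oct$tetramer1],
      label = "interface"))
    low <- seq_len(min(config$gnm$lowModes, config$gnm$modes))
    report$gnm <- list(
      tetramer = profT$profile, octamer = profO$profile,
      cPocketLowTetramer = mean(profT$profile$C[low]),
      cPocketLowOctamer = mean(profO$profile$C[low]),
      cInterfaceTetramer = correlationProfile(spT, junTetIdx,
                                              config$gnm$modes,
                                              minParticipation = mp),
      cInterfaceOctamer = correlationProfile(spO, junIdx, config$gnm$modes,
                                             minParticipation = mp),
      zeroModes = c(tetramer = nZeroModes(spT), octamer = nZeroModes(spO)))
  }

  if ("dmd" %in% stages) {
    say("DMD simulations")
    runSystem <- function(ca, pockets, seedOffset, contacts = NULL) {
      if (is.null(contacts))
        contacts <- nativeContacts(ca, config$contacts$cutoff,
                                   config$contacts$minSeqSep)
      model <- buildGoModel(ca, contacts)
      trajs <- runReplicas(model, config$dmd$nSteps,
                           replicas = config$dmd$replicas,
                           baseSeed = config$seed + seedOffset,
                           temperature = config$dmd$temperature,
                           snapshotEvery = config$dmd$snapshotEvery,
                           thermostatRate = config$dmd$thermostatRate)
      perPocket <- lapply(pockets, function(idx)
        drmsProfile(trajs, model, idx, config$dmd$burnInFraction))
      vals <- unlist(lapply(perPocket, function(p) p$perFrame$drms))
      list(mean = mean(vals), sd = sd(vals),
           perPocketMean = vapply(perPocket, `[[`, numeric(1), "mean"))
    }
    dT <- runSystem(caT, pockT, 100L)
    dO <- runSystem(caO, pockO, 200L, contacts = oct$goContacts)
    report$dmd <- list(tetramer = dT, octamer = dO,
                      drmsMeanTetramer = dT$mean, drmsMeanOctamer = dO$mean)
  }

  if ("interface" %in% stages) {
    say("buried interface areas")
    areaT1L <- buriedInterfaceArea(oct$structure, oct$tetramer1,
                                   oct$linkers, config$sasa$probe,
                                   config$sasa$nPoints)
    areaT1T2 <- buriedInterfaceArea(oct$structure, oct$tetramer1,
                                    oct$tetramer2, config$sasa$probe,
                                    config$sasa$nPoints)
    areaSS <- buriedInterfaceArea(oct$structure, oct$linkers[1],
                                  oct$linkers[2], config$sasa$probe,
                                  config$sasa$nPoints)
    census <- interfaceCensus(oct$structure, oct$tetramer1, oct$linkers,
                              probe = config$sasa$probe,
                              nPoints = config$sasa$nPoints)
    report$interface <- list(
      tetramerLinker = interfaceArea(areaT1L),
      tetramerTetramer = interfaceArea(areaT1T2),
      linkerLinker = interfaceArea(areaSS),
      censusCount = census$count)
  }

  if ("filament" %in% stages) {
    say("filament reconstruction")
    rod <- makeRodUnit(config$synth$nRes, seed = config$seed)
    helix <- makeHelicalFixture(rod, twist = config$filament$twist,
                                rise = config$filament$rise, kink = 0,
                                n = config$filament$nCopies)
    screw <- screwDecompose(helix$transform)
    kinked <- makeHelicalFixture(rod, twist = 0.5,
                                 rise = config$filament$rise,
                                 kink = config$filament$kink, n = 2L)
    pair <- filamentStructure(kinked$filament)
    report$filament <- list(
      twist = screw@twist, rise = screw@rise,
      repeatsPerTurn = screw@repeatsPerTurn,
      handedness = screw@handedness,
      kink = kinkAngle(pair, "A1", "A2", "inertia"),
      truth = list(twist = config$filament$twist,
                   rise = config$filament$rise,
                   kink = config$filament$kink))
  }

  report
}

#' Write an analysis report
#'
#' JSON master file plus one TSV per tabular stage output.
#'
#' @param report list from [runAnalysis()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scalar <- report
  if (!is.null(scalar$gnm)) {
    write.table(scalar$gnm$tetramer, file.path(dir, "cpocket_tetramer.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(scalar$gnm$octamer, file.path(dir, "cpocket_octamer.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    scalar$gnm$tetramer <- scalar$gnm$octamer <- NULL
    scalar$gnm$cInterfaceTetramer <- scalar$gnm$cInterfaceOctamer <- NULL
  }
  jsonlite::write_json(scalar, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
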