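#' @include AllClasses.R
NULL

#' Run the full characterization pipeline on synthetic fixtures
#'
#' Deterministic end-to-end replay: generates every synthetic input with
#' streams derived from one global seed, runs each analysis stage in
#' dependency order (quantitation, kinetics, diffusion, lattice geometry,
#' porosimetry, tomography, indentation, thermal), and writes one JSON
#' report per stage plus a combined `summary.json` (all carrying the seed
#' and package version) and per-stage CSVs of the generated inputs.
#'
#' `config` overrides per-stage defaults; recognised entries:
#' `stages` (character vector to run; default all),
#' `kinetics` (list: `qEMip`, `k2Mip`, `qENip`, `k2Nip`, `noiseSd`),
#' `diffusion` (list: `dMip`, `dNip`, `l`, `alpha`, `nTerms`),
#' `lattice` (list: `resolution` mm),
#' `porosimetry` (list: `medianNm`, `sigmaLog10`, `totalVolume`,
#' `skeletalDensity`),
#' `tomography` (list: `shape`, `targetPorosity`, `correlationLength`),
#' `mechanics` (list: `targetEsMip`, `targetEsNip`, `pMax`),
#' `thermal` (list: `tg`, `noiseFrac`).
#'
#' @param outDir output directory (created if missing).
#' @param seed global integer seed; every stage derives its own stream.
#' @param config optional named list (or path to a JSON file) of overrides.
#' @return invisibly, the summary list.
#' @export
runPipeline <- function(outDir, seed = 42L, config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  defaults <- list(
    stages = c("quantitation", "kinetics", "diffusion", "lattice",
               "porosimetry", "tomography", "mechanics", "thermal"),
    kinetics = list(qEMip = 3.61, k2Mip = 0.0049, qENip = 1.31,
                    k2Nip = 0.0092, noiseSd = 0.1),
    diffusion = list(dMip = 3.9e-13, dNip = 2.5e-13, l = 190e-6,
                     alpha = 0.4402, nTerms = 6L),
    lattice = list(resolution = 0.05),
    porosimetry = list(medianNm = 44, sigmaLog10 = 0.5, totalVolume = 0.609,
                       skeletalDensity = 1.343),
    tomography = list(shape = c(64L, 64L, 64L), targetPorosity = 46,
                      correlationLength = 8),
    mechanics = list(targetEsMip = 93, targetEsNip = 74, pMax = 400),
    thermal = list(tg = 140.3, noiseFrac = 0.02))
  cfg <- utils::modifyList(defaults, config)
  summary <- list(seed = seed,
                  package_version = as.character(utils::packageVersion("porolith")))
  emit <- function(stage, x) {
    jsonlite::write_json(x, file.path(outDir, paste0(stage, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    x
  }

  if ("quantitation" %in% cfg$stages) {
    tab <- genCalibration(noiseSd = 1e-3, seed = seed)
    utils::write.csv(tab, file.path(outDir, "calibration.csv"),
                     row.names = FALSE)
    cal <- fitCalibration(tab$concentration_mmol_per_L, tab$absorbance)
    exp <- bindingExperiment(cIncubation = 2.4e-5, vIncubation = 0.1,
                             vElution = 0.003,
                             cElution = absorbanceToConcentration(
                               cal, cal@slope * 0.2472 + cal@intercept),
                             polymerMass = 0.15)
    br <- bindingResult(exp)
    summary$quantitation <- emit("quantitation", list(
      seed = seed, calibration_slope = cal@slope,
      calibration_r_squared = cal@rSquared,
      q_mg_per_g = br$qMean, enrichment_factor = br$enrichmentFactor))
  }

  if ("kinetics" %in% cfg$stages) {
    k <- cfg$kinetics
    fits <- lapply(list(MIP = c(k$qEMip, k$k2Mip), NIP = c(k$qENip, k$k2Nip)),
                   function(p) {
      s <- genUptake("PSO", list(qE = p[1], k2 = p[2]), noiseSd = k$noiseSd,
                     seed = seed)
      writeUptakeCsv(s, file.path(outDir, paste0("uptake_", p[1], ".csv")))
      f <- fitKinetics(s, "PSO")
      list(q_e = f@qE, k2 = f@k, r_squared = f@rSquared, rmse = f@rmse)
    })
    summary$kinetics <- emit("kinetics", c(list(seed = seed), fits))
  }

  if ("diffusion" %in% cfg$stages) {
    dd <- cfg$diffusion
    rec <- lapply(list(MIP = dd$dMip, NIP = dd$dNip), function(dtrue) {
      s <- genUptake("crank", list(d = dtrue, l = dd$l, alpha = dd$alpha,
                                   nTerms = dd$nTerms), seed = seed)
      f <- fitDiffusion(s, l = dd$l, alpha = dd$alpha, nTerms = dd$nTerms,
                        qInf = 1)
      list(d_generating = dtrue, d_recovered = f@dApparent,
           r_squared = f@rSquared)
    })
    summary$diffusion <- emit("diffusion", c(
      list(seed = seed,
           d_ratio = rec$MIP$d_recovered / rec$NIP$d_recovered), rec))
  }

  if ("lattice" %in% cfg$stages) {
    mets <- lapply(c("S1", "S2"), function(sh) {
      vox <- voxelize(buildLattice(latticeSpec(sh)),
                      cfg$lattice$resolution)
      m <- measureLattice(vox)
      m[c("windowsPerFace", "windowEdge", "wallThickness",
          "macroVoidFraction", "characteristicHalfThickness")]
    })
    names(mets) <- c("S1", "S2")
    summary$lattice <- emit("lattice", c(list(seed = seed), mets))
  }

  if ("porosimetry" %in% cfg$stages) {
    pp <- cfg$porosimetry
    cur <- genIntrusion(pp$medianNm, pp$sigmaLog10, pp$totalVolume,
                        noiseFrac = 0.01, seed = seed)
    utils::write.csv(data.frame(pressure_Pa = cur@pressures,
                                cumulative_volume_cm3_per_g =
                                  cur@cumulativeVolume),
                     file.path(outDir, "intrusion.csv"), row.names = FALSE)
    psd <- invertIntrusion(cur)
    summary$porosimetry <- emit("porosimetry", list(
      seed = seed, median_nm = psd@medianDiameter,
      modal_nm = psd@modalDiameter,
      total_volume_cm3_per_g = psd@totalSpecificVolume,
      porosity_percent = totalPorosity(psd@totalSpecificVolume,
                                       pp$skeletalDensity)))
  }

  if ("tomography" %in% cfg$stages) {
    tg_ <- cfg$tomography
    vol <- genVolume(shape = tg_$shape, targetPorosity = tg_$targetPorosity,
                     correlationLength = tg_$correlationLength, seed = seed)
    seg <- binarize(vol$stack, threshold = 110)
    conn <- connectivity(vol$truth)
    summary$tomography <- emit("tomography", list(
      seed = seed,
      porosity_truth_percent = porosityFraction(vol$truth),
      porosity_segmented_percent = porosityFraction(seg),
      largest_component_fraction_percent = conn$largestComponentFraction,
      face_spanning = conn$faceSpanning))
  }

  if ("mechanics" %in% cfg$stages) {
    mm <- cfg$mechanics
    res <- lapply(list(MIP = mm$targetEsMip, NIP = mm$targetEsNip),
                  function(es) {
      cur <- genIndentation(es, pMax = mm$pMax, seed = seed)
      r <- oliverPharr(cur)
      list(e_s_target = es, e_s = r@sampleModulus,
           e_r = r@reducedModulus, hardness = r@hardness)
    })
    summary$mechanics <- emit("mechanics", c(list(seed = seed), res))
  }

  if ("thermal" %in% cfg$stages) {
    th <- cfg$thermal
    tr <- genDsc(tg = th$tg, noiseSd = abs(th$noiseFrac * 0.3), seed = seed)
    r <- tgMidpoint(tr)
    summary$thermal <- emit("thermal", list(
      seed = seed, tg = r$tg, onset = r$onset, endset = r$endset,
      step_height = r$stepHeight))
  }

  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
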