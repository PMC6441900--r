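# Phenotype presets: parameter sets emulating developing, adult and
# failing (HF) cardiomyocytes. Values are illustrative study conditions
# motivated by the developmental and disease phenotypes the pipelines are
# meant to resolve (sparse, longitudinal-dominant networks with slow,
# dyssynchronous release in developing cells; dense transverse networks
# with tight dyadic coupling and fast synchronous release in adult cells;
# reduced transverse density, orphaned gaps and propagation-limited release
# in HF), not fits to any particular data set.

#' Phenotype preset specifications for the synthetic generators
#'
#' @param phenotype "developing", "adult" or "hf"
#' @param modality "tubules", "dyads", "calcium" or "voltage"
#' @param seed RNG seed stored in the returned spec
#' @return a spec object for the matching \code{generate*} function
#' @export
phenotypePreset <- function(phenotype = c("developing", "adult", "hf"),
                            modality = c("tubules", "dyads", "calcium",
                                         "voltage"),
                            seed = 1L) {
  phenotype <- match.arg(phenotype)
  modality <- match.arg(modality)
  net <- switch(phenotype,
    developing = tubuleNetworkSpec(transverseOccupancy = 0.3,
                                   longitudinalDensityPerUm2 = 0.08,
                                   cellLengthUm = 24, cellWidthUm = 11,
                                   seed = seed),
    adult = tubuleNetworkSpec(transverseOccupancy = 0.9,
                              longitudinalDensityPerUm2 = 0.03,
                              cellLengthUm = 28, cellWidthUm = 13,
                              seed = seed),
    hf = tubuleNetworkSpec(transverseOccupancy = 0.55,
                           longitudinalDensityPerUm2 = 0.1,
                           cellLengthUm = 28, cellWidthUm = 13,
                           seed = seed))
  if (modality == "tubules") return(net)
  if (modality == "dyads") {
    dnet <- function(occ, long) {
      tubuleNetworkSpec(cellLengthUm = 16, cellWidthUm = 8,
                        pixelSizeUm = 0.05, marginUm = 1.2,
                        psfSigmaUm = 0.1, transverseOccupancy = occ,
                        longitudinalDensityPerUm2 = long, seed = seed)
    }
    return(switch(phenotype,
      developing = dyadSpec(network = dnet(0.9, 0.12), ryrOccupancy = 0.5,
                            colocFractionTransverse = 0.85,
                            colocFractionLongitudinal = 0.5, seed = seed),
      adult = dyadSpec(network = dnet(0.9, 0.04), ryrOccupancy = 0.9,
                       colocFractionTransverse = 0.9,
                       colocFractionLongitudinal = 0.3, seed = seed),
      hf = dyadSpec(network = dnet(0.9, 0.1), ryrOccupancy = 0.6,
                    colocFractionTransverse = 0.55,
                    colocFractionLongitudinal = 0.3, orphanGapCount = 4L,
                    seed = seed)))
  }
  cnet <- function(occ, long) {
    tubuleNetworkSpec(cellLengthUm = 18, cellWidthUm = 9, marginUm = 1.5,
                      transverseOccupancy = occ,
                      longitudinalDensityPerUm2 = long, seed = seed)
  }
  if (modality == "calcium") {
    return(switch(phenotype,
      developing = calciumSpec(network = cnet(0.35, 0.12), riseTauMs = 16,
                               siteDelayMeanMs = 10, siteDelaySdMs = 8,
                               orphanPropagationSpeedUmPerMs = 0.1,
                               seed = seed),
      adult = calciumSpec(network = cnet(0.9, 0.03), riseTauMs = 6,
                          siteDelayMeanMs = 3, siteDelaySdMs = 2,
                          orphanPropagationSpeedUmPerMs = 0.5,
                          seed = seed),
      hf = calciumSpec(network = cnet(0.55, 0.08), riseTauMs = 16,
                       siteDelayMeanMs = 12, siteDelaySdMs = 10,
                       orphanPropagationSpeedUmPerMs = 0.08,
                       seed = seed)))
  }
  switch(phenotype,
    developing = voltageSpec(network = cnet(0.35, 0.12),
                             depolarizedFraction = 0.95, seed = seed),
    adult = voltageSpec(network = cnet(0.9, 0.03),
                        depolarizedFraction = 0.97, seed = seed),
    hf = voltageSpec(network = cnet(0.55, 0.08),
                     depolarizedFraction = 0.6, seed = seed))
}
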