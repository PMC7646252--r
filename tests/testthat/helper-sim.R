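# Shared tiny fixtures built in code.

tinyDesign <- function(n = 2L, ...) {
    cassetteDesign(nSegments = n, ...)
}

# a noise-free configuration for small end-to-end runs (no size selection,
# so short small-design products survive)
cleanConfig <- function(nFounders = 6L, cellsSampled = 12L, expansion = 4L,
                        readsPerCell = 40, seed = 101L, ...) {
    simConfig(nFounders = nFounders, cellsSampled = cellsSampled,
              expansion = expansion, readsPerCell = readsPerCell,
              readsDispersion = Inf, subRate = 0, insRate = 0, delRate = 0,
              truncationProb = 0, contaminationRate = 0,
              ampliconMin = 0, ampliconMax = Inf, seed = seed, ...)
}

truthTable <- function(sim) {
    merge(sim$truth$cells, sim$truth$founders, by = "founder_id")
}

# annotated-cell table straight from simulation truth (linkage-level tests)
truthAnnotated <- function(sim) {
    tt <- truthTable(sim)
    data.frame(cell_id = tt$cell_id, lineage = tt$lineage,
               polylox = tt$polylox, uci = tt$uci,
               timestamp = paste(tt$polylox, tt$uci, sep = ":"),
               stringsAsFactors = FALSE)
}
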