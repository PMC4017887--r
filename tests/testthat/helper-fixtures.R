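# Shared, lazily computed fixtures.  The expensive objects (Hopf
# scans, spreading-depression threshold searches, anoxia runs) are
# computed once per test session and reused across files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]]))
    assign(name, force(expr), envir = .fixtures)
  .fixtures[[name]]
}

hopf_fixture <- function(genotype, f = 3) {
  fixture(sprintf("hopf_%s_f%g", genotype, f),
          scan_hopf(genotype = genotype, f = f))
}

sd_threshold_fixture <- function(genotype, f = 3) {
  fixture(sprintf("sdthr_%s_f%g", genotype, f),
          find_sd_threshold(genotype = genotype, f = f))
}

# threshold run re-simulated with fine sampling for spike-level work
sd_threshold_run_fine <- function(genotype, f = 3) {
  fixture(sprintf("sdrun_%s_f%g", genotype, f), {
    thr <- sd_threshold_fixture(genotype, f)
    run_pump_interruption(thr$threshold_s, genotype, f = f,
                          dt_ms = 0.25)
  })
}

decapitation_fixture <- function(genotype) {
  fixture(sprintf("decap_%s", genotype),
          run_decapitation(genotype = genotype))
}
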