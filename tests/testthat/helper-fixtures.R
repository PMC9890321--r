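# Rendered synthetic corpora are built once per test run and cached here.
fixture_cache <- new.env(parent = emptyenv())

# Small rendered corpus with coarticulation shifts on LH (tone frequency when
# preceding DS) and NL (band position when combined with other segments).
fixture_corpus <- function(name = "base", n_combinations = 60,
                           n_individuals = 6, n_groups = 4, seed = 11,
                           coart = NULL) {
  if (is.null(fixture_cache[[name]])) {
    spec <- generator_spec(n_combinations = n_combinations,
                           n_individuals = n_individuals,
                           n_groups = n_groups, seed = seed)
    man <- sample_sequences(spec)
    if (!is.null(coart)) man <- inject_coarticulation(man, coart)
    dir <- file.path(tempdir(), paste0("vocalcomb-fixture-", name))
    render_audio(man, spec, dir)
    fixture_cache[[name]] <- list(spec = spec, manifest = man, dir = dir,
                                  corpus = read_corpus(dir))
  }
  fixture_cache[[name]]
}

coart_rules <- function() {
  list(list(class = "LH", category = "precedes-DS", freq_shift = 800),
       list(class = "NL", category = "combined", band_shift = 900))
}

# hand-built two-call annotation: NL-DS call then LH-DS call, one combination
tiny_annotation <- function() {
  meta <- recording_meta("recA", "ind1", "grp1", "site A", "F")
  segments <- data.frame(
    label = c("NL", "DS", "LH", "DS"),
    start = c(0.10, 0.21, 0.75, 1.06),
    end   = c(0.20, 0.35, 1.05, 1.20))
  calls <- data.frame(label = c("NL-DS", "LH-DS"),
                      start = c(0.10, 0.75), end = c(0.35, 1.20))
  combs <- data.frame(label = "NL-DS LH-DS", start = 0.10, end = 1.20)
  annotation_set(meta, segments, calls, combs)
}
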