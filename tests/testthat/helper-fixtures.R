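# shared fixtures, built once per test run and cached

.fixture_env <- new.env(parent = emptyenv())

shared_manifest <- function(seed = 3L) {
  key <- paste0("man", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- default_manifest(seed = seed)
  .fixture_env[[key]]
}

shared_catalog <- function(seed = 3L) {
  key <- paste0("cat", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- manifest_catalog(shared_manifest(seed))
  .fixture_env[[key]]
}

shared_run <- function(seed = 3L, n = 30000L) {
  key <- paste0("run", seed, "_", n)
  if (is.null(.fixture_env[[key]])) {
    man <- shared_manifest(seed)
    sim <- simulate_reads(man, n, seed = seed)
    res <- suppressWarnings(
      run_pipeline(sim$reads, shared_catalog(seed), foreign = man$foreign))
    .fixture_env[[key]] <- list(man = man, sim = sim, res = res)
  }
  .fixture_env[[key]]
}

random_dna <- function(n, len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE, prob = p), collapse = ""),
    character(1))
}

expression_fixture <- function() {
  path <- system.file("extdata", "rmec_mirna_expression.tsv",
                      package = "srnatlas")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
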