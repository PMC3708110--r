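#!/usr/bin/env Rscript
# Reduce the raw library to a workable tag list: clip the 3' adapter, keep
# reads over 15 nt, collapse to unique sequences, and drop tags seen fewer
# than 3 times. The retained-read fraction shows how little signal the
# abundance filter costs, and the length histogram shows the miRNA peak at
# ~22 nt with the minor snoRNA/tRF shoulder at 28-30 nt.

suppressMessages(library(srnatlas))

out <- "results/analysis"
man <- default_manifest(seed = 2026L)
reads <- read_fastq(file.path(out, "library.fastq"))

cas <- read_cascade(unname(reads), man$adapter)
write.table(data.frame(step = names(cas$cascade), value = unlist(cas$cascade)),
            file.path(out, "cascade.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_collapsed_tsv(cas$library, file.path(out, "tags.tsv"))

h <- length_histogram(cas$library)
write.table(data.frame(length = as.integer(names(h$histogram)),
                       reads = h$histogram),
            file.path(out, "length_histogram.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

expected <- read.table(file.path(out, "expected_cascade.tsv"), header = TRUE,
                       sep = "\t")
same <- all(unlist(cas$cascade[1:4]) ==
              expected$value[match(names(cas$cascade)[1:4], expected$step)])
message(sprintf("cascade: %d raw -> %d >15nt -> %d unique -> %d at >=3 reads",
                cas$cascade$raw, cas$cascade$gt_min_len, cas$cascade$unique,
                cas$cascade$unique_filtered))
message("matches generator accounting exactly: ", same)
message(sprintf("mean clipped length %.1f nt; retained read fraction %.1f%%",
                h$mean_length, 100 * cas$cascade$retained_read_fraction))
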