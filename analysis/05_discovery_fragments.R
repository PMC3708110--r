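#!/usr/bin/env Rscript
# Novel-miRNA discovery and host-derived fragments: expressed intervals from
# unannotated tags are folded and filtered (support > 100 reads, 21-23 nt
# dominant tag, single hairpin at <= -25 kcal/mol, tight one-arm pairing);
# star-strand evidence upgrades candidates to the supported tier. Orthologs
# of the foreign mature set and seed families are reported, along with
# snoRNA- and tRNA-derived fragments.

suppressMessages(library(srnatlas))

out <- "results/analysis"
man <- default_manifest(seed = 2026L)
catl <- manifest_catalog(man)
reads <- read_fastq(file.path(out, "library.fastq"))
res <- suppressWarnings(run_pipeline(unname(reads), catl,
                                     foreign = man$foreign))

cand <- res$candidates
write.table(cand, file.path(out, "novel_candidates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
pass <- cand[cand$pass, ]
message(sprintf("%d of %d evaluated intervals pass all filters (%d planted)",
                nrow(pass), nrow(cand), nrow(man$novel)))
message(sprintf("tiers: %s", paste(pass$tier, collapse = ", ")))

if (!is.null(res$orthologs)) {
  write.table(res$orthologs, file.path(out, "orthologs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf("ortholog calls: %d (best match %s)",
                  nrow(res$orthologs), res$orthologs$ortholog_of[1]))
}

fam <- assign_families(stats::setNames(man$novel$mature, man$novel$id),
                       stats::setNames(man$mirna$sequence, man$mirna$name))
write.table(fam, file.path(out, "seed_families.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
shared <- fam[fam$seed == man$family_seed, ]
message(sprintf("planted seed family recovered with %d members", nrow(shared)))

fr <- res$fragments
write.table(fr, file.path(out, "fragments.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
rep <- cluster_report(fr, man$sno_ids)
write.table(rep, file.path(out, "sno_cluster_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
dom <- rep$host_id[which.max(rep$total_reads)]
message(sprintf("snoRNA cluster: reads on all %d members; dominant %s (%d reads)",
                nrow(rep), dom, round(max(rep$total_reads))))
gly <- fr[fr$host_id == "tRNA-Gly-GCC", ]
message(sprintf("tRNA-Gly-GCC family: %d 5' fragments, %d reads",
                nrow(gly), round(sum(gly$count))))
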