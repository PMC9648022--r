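#!/usr/bin/env Rscript
# Stage-vs-normal differential expression per dataset, the cross-study
# direction-consistent unions (Sets1), stepwise-gene detection, and the
# per-dataset DEG/stepwise intersections (Sets2).

suppressMessages(library(cervstage))
dir.create("results", showWarnings = FALSE)

datasets <- lapply(1:3, function(d)
  read_expression(sprintf("results/sim/sim%d_matrix.tsv", d),
                  sprintf("results/sim/sim%d_meta.tsv", d),
                  dataset_id = sprintf("sim%d", d)))

deg_tables <- lapply(datasets, differential_expression_all)
for (i in seq_along(deg_tables))
  data.table::fwrite(deg_tables[[i]], sprintf("results/deg_sim%d.tsv", i),
                     sep = "\t")

s1 <- cross_study_sets1(deg_tables)
for (cmp in names(s1)) {
  writeLines(s1[[cmp]]$up, sprintf("results/sets1_%s_up.txt", cmp))
  writeLines(s1[[cmp]]$down, sprintf("results/sets1_%s_down.txt", cmp))
}

sets2 <- lapply(seq_along(datasets), function(i) {
  sw <- stepwise_genes(datasets[[i]])
  data.table::fwrite(sw, sprintf("results/stepwise_sim%d.tsv", i), sep = "\t")
  s2 <- cross_stage_sets2(deg_tables[[i]], sw)
  writeLines(s2$up, sprintf("results/sets2_sim%d_up.txt", i))
  writeLines(s2$down, sprintf("results/sets2_sim%d_down.txt", i))
  s2
})

counts <- list(
  deg = lapply(deg_tables, function(t) table(t$comparison, t$direction)),
  sets1 = lapply(s1, lengths), sets2 = lapply(sets2, lengths))
jsonlite::write_json(counts, "results/deg_summary.json", auto_unbox = TRUE,
                     force = TRUE)
cat(sprintf("Sets1 CN: %d up / %d down; Sets2 sizes per dataset: %s up\n",
            length(s1$CN$up), length(s1$CN$down),
            paste(vapply(sets2, function(s) length(s$up), 0), collapse = "/")))
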