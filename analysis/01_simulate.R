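#!/usr/bin/env Rscript
# Generate the synthetic input bundle that stands in for the study's
# expression datasets, interaction network, IHC cohort and survival
# cohorts.  All downstream drivers read from results/sim/.

suppressMessages(library(cervstage))
cfg <- sim_config(seed = 1)
bundle <- write_sim_bundle(cfg, "results/sim")
cat(sprintf("Simulated %d expression datasets (%d genes, %d samples each),\n",
            cfg$n_datasets, cfg$genes_total, 4 * cfg$n_per_stage))
cat(sprintf("a %d-node network with %d planted hubs, an IHC cohort of %d\n",
            cfg$network_size, cfg$n_hubs,
            cfg$ihc_n_diseased + cfg$ihc_n_controls),
    sprintf("sections and a survival cohort of %d patients.\n", cfg$surv_n))
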