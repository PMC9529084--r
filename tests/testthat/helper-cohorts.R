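# Shared simulator configurations for the test suite.

# one pan-cancer driver amplified and hazard-coupled in 3 of 5 cancers —
# the planted analogue of a recurrently amplified, overexpressed,
# survival-relevant matrisome gene
driver_table <- function(gene = "G0005", cancers = "CAN01,CAN02,CAN03",
                         amp_prob = 0.3, del_prob = 0,
                         expression_shift = 1.5, cna_coupling = 0.5,
                         log_hazard_ratio = 0.7, stage_trend = 0) {
  data.frame(gene = gene, cancers = cancers, amp_prob = amp_prob,
             del_prob = del_prob, expression_shift = expression_shift,
             cna_coupling = cna_coupling,
             log_hazard_ratio = log_hazard_ratio,
             stage_trend = stage_trend, stringsAsFactors = FALSE)
}

driver_config <- function(seed, ...) {
  sim_config(n_cancers = 5, n_tumour = 100, n_normal = 40, n_genes = 150,
             drivers = driver_table(...), seed = seed)
}

null_config <- function(seed, n_cancers = 5, n_tumour = 100, n_normal = 40,
                        n_genes = 150) {
  sim_config(n_cancers = n_cancers, n_tumour = n_tumour,
             n_normal = n_normal, n_genes = n_genes, drivers = NULL,
             seed = seed)
}

pipe_config <- function(...) {
  pipeline_config(n_cancers_denominator = NULL, ...)
}
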