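# Published diagnostic-performance reference rows (percentages with exact
# 95% CIs, PPV/NPV percentages, AUC), HSIL and HSIL+ panels, used by the
# reconstruction tests.

reference_rows <- function() ihc_reference_metrics()
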