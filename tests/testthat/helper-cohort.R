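# Deterministic 99-patient cohort reconstructed from the published group
# counts: 38 expanders (6 type I, 6 type II, 26 no endoleak) and 61
# non-expanders (1 type I, 6 type II, 54 none). Volumes are chosen so the
# 2% rule reproduces the generating group exactly.
published_counts_cohort <- function() {
  grp <- rep(c("expansion", "non_expansion"), c(38, 61))
  leak <- c(rep(c("type_I", "type_II", "none"), c(6, 6, 26)),
            rep(c("type_I", "type_II", "none"), c(1, 6, 54)))
  data.frame(id = sprintf("P%03d", 1:99), group = grp, endoleak = leak,
             V1 = 100, V2 = ifelse(grp == "expansion", 110, 95),
             stringsAsFactors = FALSE)
}

# Small phantom settings shared across tests (fast to render/extract).
small_phantom <- function(seed = 1L, ...) {
  phantom_params(image_size = 64L, sac_radius_px = 26, seed = seed, ...)
}
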