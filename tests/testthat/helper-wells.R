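# quick droplet-well constructor for tests
make_wells <- function(k, n, sample_id = "S1", target = "p190",
                       role = "sample", well_id = sprintf("W%02d", seq_along(k)),
                       replicate_group = sample_id) {
  nr <- length(k)
  data.frame(
    well_id = rep_len(well_id, nr), sample_id = rep_len(sample_id, nr),
    target = rep_len(target, nr), role = rep_len(role, nr),
    replicate_group = rep_len(replicate_group, nr),
    n_accepted = n, k_positive = k
  )
}

# background plate matching the specificity study design:
# 32 NTC replicates plus 16 replicates of each of four donor pools
make_background_plate <- function(k = 0) {
  rbind(
    make_wells(rep(k, 32), rep(15000, 32), sample_id = "NTC", role = "NTC",
               well_id = sprintf("N%02d", 1:32)),
    do.call(rbind, lapply(1:4, function(p) {
      make_wells(rep(k, 16), rep(15000, 16),
                 sample_id = sprintf("pool%d", p), role = "healthy_donor",
                 well_id = sprintf("P%d_%02d", p, 1:16))
    }))
  )
}
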