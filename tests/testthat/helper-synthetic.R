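# Shared synthetic study objects, built once per test run.

test_refs <- synthetic_references()
test_registry <- synthetic_cutoffs()

# pairs within each category across the three synthetic references
ow_pairs <- c("refA +1:refB +1.3", "refB +1.3:refC +1.04", "refC +1.04:refA +1")
ob_pairs <- c("refA +2:refB +2.3", "refB +2.3:refC +1.64", "refC +1.64:refA +2")
thin_pairs <- c("refA -2:refB -1.9", "refB -1.9:refC -1.64", "refC -1.64:refA -2")

# pure-shift pairs (refA vs refB differ by an exact z-shift)
shift_pairs <- c("refA +1:refB +1.3", "refA +2:refB +2.3", "refA -2:refB -1.9")

make_groups <- function(n_groups, n_per_group = 1000,
                        ages = seq(6, 16, length.out = ceiling(n_groups / 2))) {
  data.frame(sex = rep(c("male", "female"), length.out = n_groups),
             mean_age = rep(ages, each = 2)[seq_len(n_groups)],
             n = n_per_group)
}

# records lying exactly on the conversion (counts quantized only by n)
exact_records <- function(n_groups = 20, n_per_group = 1e6, z_shift = 0.25,
                          pairs = shift_pairs, seed = 1) {
  dat <- simulate_prevalence_dataset(make_groups(n_groups, n_per_group),
                                     test_refs, test_registry, pairs,
                                     z_shift = z_shift, seed = seed,
                                     return_truth = TRUE)
  dat$prev_A <- dat$true_prev_A
  dat$prev_B <- dat$true_prev_B
  dat$true_prev_A <- dat$true_prev_B <- NULL
  stack_records(dat, refs = test_refs, registry = test_registry)
}
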