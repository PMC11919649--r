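# Shared fixtures: the packaged protocol and its (expensive-ish) kernel are
# built once per test run; a reduced cohort spec keeps pipeline smoke tests
# fast.

.fixtures <- new.env()

test_prot <- function() {
  if (is.null(.fixtures$prot)) .fixtures$prot <- default_protocol()
  .fixtures$prot
}

# microstructural subset (the sequences with printed b-value lists)
test_prot_micro <- function() {
  p <- test_prot()
  p$sequences <- p$sequences[c("PGSE", "OGSE_17Hz", "OGSE_33Hz")]
  p
}

test_kernel <- function() {
  if (is.null(.fixtures$kernel)) .fixtures$kernel <- impulsed_kernel(test_prot())
  .fixtures$kernel
}

# noiseless forward signal table in the shape fit_impulsed() consumes
forward_df <- function(d_mean, f_in, D_ex, prot = test_prot(),
                       kernel = test_kernel()) {
  s <- two_compartment_signal(list(d_mean = d_mean, f_in = f_in, D_ex = D_ex,
                                   D_in = kernel$D_in),
                              prot, kernel = kernel)
  data.frame(sequence = s$sequence, b = s$b, S = s$S_over_S0)
}

small_spec <- function() {
  cohort_spec(
    n_collected = 30,
    exclusions = c(small_lesion = 2, no_pathology = 1, poor_quality = 1),
    n_benign = 12, n_malignant = 14,
    benign_histology = c(Fibroadenoma = 12),
    malignant_histology = c(InvasiveCarcinoma = 10, DCIS = 4),
    ihc = list(er_pos = 7, pr_pos = 6, her2_pos = 4, ki67_high = 8,
               grade = c(I = 1, II = 5, III = 4),
               subtype = c(LuminalA = 1, LuminalB = 5, HER2over = 2, TN = 2)))
}
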