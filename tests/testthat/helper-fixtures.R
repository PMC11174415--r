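# Shared fixtures: a down-scaled configuration and matching synthetic
# data keep the unit tests fast while exercising every stage.

tiny_config <- function(...) {
  sogpcn_config(montage = paste0("C", 1:4), padded_length = 12L,
                k = 3L, embed_dim = 3L, graph_out = 8L, n_maps = 2L,
                conv1_kernel = c(3L, 3L, 3L), conv1_stride = c(1L, 1L, 1L),
                conv1_pad = c(1L, 1L, 1L), lstm_hidden = 4L, dropout = 0,
                ...)
}

tiny_spec <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 3, trials_per_subject = 6,
         montage = paste0("C", 1:4), length_range = c(10L, 12L),
         planted_degree = 2L),
    list(...))
  do.call(synthetic_spec, args)
}

# a small trial with labelled axes for channel/band selection tests
labelled_trial <- function(N = 6, M = 5, T = 8, channels = NULL) {
  if (is.null(channels)) channels <- seed_montage(12)[seq_len(N)]
  de_trial(array(seq_len(N * M * T), c(N, M, T)),
           label = 1L, subject = 2L,
           channels = channels, bands = seed_bands()$name[seq_len(M)])
}

expect_rows_sum_to_one <- function(m, tol = 1e-6) {
  expect_true(all(abs(rowSums(m) - 1) < tol))
}
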