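# Shared small simulation fixture, built once per test run (in code, no
# stored data). 150 kb, 8 parent genes, 9 planted retrocopies of all three
# classes, decoy negatives.

.fixture_env <- new.env(parent = emptyenv())

small_config <- function() {
  sim_config(genome_length = 150000, n_parent_genes = 8,
             n_retro_intact = 3, n_retro_pseudo = 2, n_retro_chimeric = 4,
             n_single_exon_decoys = 1, n_decoy_retro = 1, seed = 7)
}

shared_sim <- function() {
  if (is.null(.fixture_env$sim)) .fixture_env$sim <- generate_genome(small_config())
  .fixture_env$sim
}

shared_result <- function() {
  if (is.null(.fixture_env$res)) .fixture_env$res <- run_pipeline(shared_sim())
  .fixture_env$res
}

shared_reads <- function() {
  if (is.null(.fixture_env$reads)) .fixture_env$reads <- sample_ests(shared_sim())
  .fixture_env$reads
}

shared_placements <- function() {
  if (is.null(.fixture_env$pl)) {
    .fixture_env$pl <- place_ests(map_ests(shared_reads()$ests,
                                           shared_sim()$genome))
  }
  .fixture_env$pl
}
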