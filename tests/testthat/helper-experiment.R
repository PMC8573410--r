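# The end-to-end desk experiment is the single expensive fixture of the
# suite; it is trained once and shared by every test that inspects it.
.exp_cache <- new.env(parent = emptyenv())

desk_experiment <- function() {
  if (is.null(.exp_cache$ex))
    .exp_cache$ex <- run_phantom_experiment(master_seed = 11)
  .exp_cache$ex
}
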