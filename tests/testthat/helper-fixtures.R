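# Shared, lazily-built fixtures.  The heavy objects (induced reentrant
# states, attenuation fields) are computed once per test session and
# reused across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(build)
  .fixtures[[name]]
}

desk_tissue <- function() {
  fixture("desk_tissue", make_tissue(slab_preset("ventricular-desk")))
}

desk_operator <- function() {
  fixture("desk_A", assemble_diffusion(desk_tissue()))
}

desk_induction <- function() {
  fixture("desk_induction", {
    ind <- induce_reentry(desk_tissue(), A = desk_operator())
    stopifnot(isTRUE(ind$inducible))
    ind
  })
}

desk_sweep <- function() {
  fixture("desk_sweep", run_defib_sweep(
    desk_tissue(), desk_induction(),
    opsins = c("GtACR1", "ChR2-RED", "ChR2"),
    irradiances = c(0.05, 0.5, 5), onsets = c(0, 100, 200)))
}

# small atrial-like slab for transmural-forcing checks
atrial_slab <- function() {
  fixture("atrial_slab", make_tissue(
    geometry_spec("atrial", lateral = 6.75, thickness = 2.25,
                  spacing = 0.45)))
}

# cheap single-cell resting states are cached by init_resting() itself
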