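# Shared fixtures, memoised so expensive objects (assembled operators,
# pacing checkpoints) are built once per test session.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!is.null(.fx[[name]])) return(.fx[[name]])
  .fx[[name]] <- force(expr)
  .fx[[name]]
}

slab_ops_detached <- function() fixture("slab_det", standard_slab_ops("detached"))

slab_ops_attached <- function() fixture("slab_att", standard_slab_ops("attached"))

slab_checkpoints <- function(cis = c(240, 340)) {
  key <- paste0("cp", paste(cis, collapse = "_"))
  fixture(key, precondition_and_checkpoint(slab_ops_detached(),
                                           pacing_spec(cis = cis)))
}

equilibrated_default <- function() fixture("eq_default",
                                           equilibrate_membrane(membrane_params()))

# small passive strand operators for cable tests
strand_ops_passive <- function(n = 60, spacing = 250, Gm = 0.05) {
  key <- paste0("strand", n, "_", spacing, "_", Gm)
  fixture(key, {
    g <- build_tissue_sheet(c(n, 1), spacing)
    fib <- structure(list(cells = tissue_cells(g),
                          vectors = matrix(rep(c(1, 0), n), ncol = 2,
                                           byrow = TRUE),
                          depth = rep(0.5, n)), class = "fiber_field")
    build_operators(g, fib, conductivity_set(),
                    membrane_params("passive", Gm = Gm))
  })
}
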