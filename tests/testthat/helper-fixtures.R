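# Shared fixtures, built in code and memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# default 48^3 translocon-like phantom at 5 A/voxel
fx_spec <- function() memo("spec48", phantom_spec())
fx_phantom <- function() memo("phantom48", build_phantom(fx_spec()))

# compact 32^3 phantom at 7.5 A/voxel (same 240 A extent, faster)
fx_spec_small <- function() memo("spec32", phantom_spec(32, 7.5))
fx_phantom_small <- function() memo("phantom32", build_phantom(fx_spec_small()))

fx_wedge <- function() wedge_spec()

# a single, compact Gaussian blob map fully inside an empty box; shifts of
# this object are free of wrap-around edge effects
fx_blob <- function(n = 32) memo(paste0("blob", n), {
  spec <- phantom_spec(n, 7.5, components = data.frame(
    name = "blob", x = 0, y = 0, z = 0, sd = 20, amplitude = 1),
    membrane = NULL)
  build_phantom(spec)
})

# adjusted Rand index between two labelings (independent oracle for
# planted-partition recovery)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# ground-truth poses (particle -> reference frame) from a generator table
gt_poses <- function(gt) {
  lapply(seq_len(nrow(gt)), function(i)
    invert_transform(rigid_transform(gt$phi[i], gt$theta[i], gt$psi[i],
                                     c(gt$dx[i], gt$dy[i], gt$dz[i]))))
}
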