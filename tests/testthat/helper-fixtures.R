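# Shared fixtures, built once per test run. All geometry is generated in
# code; nothing is read from disk.

# a single regular tetrahedron with unit edge, centred near the origin
regular_tet_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
             c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  tet_mesh(v, matrix(1:4, 1), "SOLUTE")
}

# unit right tetrahedron (0,0,0),(1,0,0),(0,1,0),(0,0,1)
unit_right_tet <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           matrix(1:4, 1), "SOLUTE")
}

# small Born fixture used by several suites (coarse to keep tests fast)
small_born_spec <- function() born_spec(subdiv = 1, n_outer = 8)

.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

small_born_mesh <- function() cached("born", make_born_mesh(small_born_spec()))

small_channel <- function()
  cached("channel", make_channel_system(channel_spec(
    box_half = 20, z_half = 30, n = c(12, 12, 18))))

small_box <- function()
  cached("box", make_box_mesh(c(-10, -10, -10), c(10, 10, 10), c(6, 6, 6)))
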