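# Shared fixtures, built once per test run and cached.  Everything is
# generated in code; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fixture_toy <- function() {
  if (is.null(.fx$toy)) .fx$toy <- make_toy_protein()
  .fx$toy
}

fixture_media <- function() {
  if (is.null(.fx$media)) {
    .fx$media <- calibrate_default_media(fixture_toy(), n_orient = 144)
  }
  .fx$media
}

fixture_two_state <- function() {
  if (is.null(.fx$two)) {
    .fx$two <- make_two_state_ensemble(fixture_toy(), 200, seed = 42)
  }
  .fx$two
}

fixture_rdc <- function() {
  if (is.null(.fx$rdc)) {
    .fx$rdc <- make_rdc_tables(fixture_two_state()$ensemble, fixture_toy(),
                               fixture_media(), seed = 43, n_orient = 144)
  }
  .fx$rdc
}

# a small all-atom-ish conformation with arbitrary but reproducible
# coordinates; n residues, one N and one H per residue
toy_conf <- function(n = 6, seed = 1) {
  set.seed(seed)
  atoms <- data.frame(chain = "A", resno = rep(seq_len(n), each = 2),
                      resid = "ALA", elety = rep(c("N", "H"), n),
                      elesy = rep(c("N", "H"), n),
                      stringsAsFactors = FALSE)
  xyz <- matrix(rnorm(6 * n, sd = 4), 2 * n, 3)
  conformation(atoms, xyz)
}

# conformations of the toy protein posed at given breathing angles by
# rotating the beta-domain in-plane about its pivot
frames_at_thetas <- function(toy, thetas) {
  rows <- rdcscape:::domain_atom_rows(toy, "B")
  lapply(thetas, function(th) {
    f <- function(phi) {
      xyz <- rdcscape:::rotate_domain_xyz(toy$conformation$xyz, rows,
                                          toy$pivots["B"], c(0, 0, 1), phi)
      breathing_angle(conformation(toy$conformation$atoms, xyz), toy$regions) - th
    }
    phi <- stats::uniroot(f, c(-80, 80), tol = 1e-12)$root
    xyz <- rdcscape:::rotate_domain_xyz(toy$conformation$xyz, rows,
                                        toy$pivots["B"], c(0, 0, 1), phi)
    conformation(toy$conformation$atoms, xyz)
  })
}

# random proper rotation matrix
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

apply_rigid <- function(conf, R = diag(3), t = c(0, 0, 0)) {
  conformation(conf$atoms, sweep(conf$xyz %*% t(R), 2, t, `+`))
}
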