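# in-code fixtures and brute-force oracles shared across tests

# fixed-column PDB record
pdb_atom_line <- function(serial, name, resname, chain, resnum, x, y, z,
                          occ = 1, b = 0, element = "C", alt = "",
                          inscode = "", hetero = FALSE) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (hetero) "HETATM" else "ATOM", serial,
          if (nchar(name) < 4) paste0(" ", name) else name,
          alt, resname, chain, resnum, inscode, x, y, z, occ, b, element)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# mixed RNA/protein fixture: chain A = 4 RNA residues with P + O atoms,
# chain B = protein residues 10-22 with CA
mixed_model_fixture <- function() {
  lines <- character()
  s <- 1
  for (i in 1:4) {
    lines <- c(lines,
      pdb_atom_line(s, "P", "A", "A", i, i * 6, 0, 0, element = "P"),
      pdb_atom_line(s + 1, "O5'", "A", "A", i, i * 6 + 1, 1, 0, element = "O"))
    s <- s + 2
  }
  for (r in 10:22) {
    lines <- c(lines,
      pdb_atom_line(s, "CA", "LEU", "B", r, r * 3, 10, 5, element = "C"))
    s <- s + 1
  }
  read_model(write_pdb_fixture(lines))
}

# random protein CA cloud as an atomic-model tibble, built in memory
random_model <- function(n, seed, spread = 10) {
  withr::with_seed(seed, {
    tibble::tibble(
      serial = seq_len(n), name = "CA", element = "C",
      resname = rep_len(c("LEU", "ALA", "VAL", "GLY"), n),
      chain = "A", resnum = seq_len(n), inscode = "", alt = "",
      x = stats::runif(n, -spread, spread),
      y = stats::runif(n, -spread, spread),
      z = stats::runif(n, -spread, spread),
      occupancy = 1, bfactor = 0, hetero = FALSE
    )
  })
}

# O(n^2) Shrake-Rupley oracle: every atom against every other, no
# neighbor search, same deterministic point set as the implementation
sasa_oracle <- function(model, probe = 1.4, n_points = 240) {
  m <- canonical_conformer(model)
  radii <- vdw_radius(m$element) + probe
  xyz <- as.matrix(m[, c("x", "y", "z")])
  pts <- cryoquant:::sphere_points(n_points)
  n <- nrow(m)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * radii[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, nrow(p))
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & d2 >= radii[j]^2
    }
    areas[i] <- mean(acc) * 4 * pi * radii[i]^2
  }
  areas
}

# exhaustive minimum cross-distance
min_distance_oracle <- function(xa, xb) {
  best <- Inf
  for (i in seq_len(nrow(xa))) {
    for (j in seq_len(nrow(xb))) {
      best <- min(best, sqrt(sum((xa[i, ] - xb[j, ])^2)))
    }
  }
  best
}
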