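# Shared in-code fixtures.

write_smi <- function(lines, ext = ".smi") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A consistent little triangle map A-B-C with unit similarities.
triangle_map <- function() {
  perturbation_map(
    c("A", "B", "C"),
    data.frame(source = c("A", "B", "A"), target = c("B", "C", "C"),
               similarity = 1)
  )
}

triangle_edges <- function(ddg = c(1, 1, 3), se = c(0, 0, 0)) {
  data.frame(edge = c("A->B", "B->C", "A->C"), ddg = ddg, se = se,
             stringsAsFactors = FALSE)
}

benzene <- function() parse_smiles("c1ccccc1", "benzene")
toluene <- function() parse_smiles("Cc1ccccc1", "toluene")

# Planar hexagon coordinates for benzene-like tests.
hexagon_coords <- function(radius = 1.4) {
  ang <- 2 * pi * (0:5) / 6
  cbind(radius * cos(ang), radius * sin(ang), 0)
}
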