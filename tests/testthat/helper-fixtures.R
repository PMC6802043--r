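# Small fixtures built in code.

# 10x10 grid with a linear climate gradient; `shift` emulates uniform
# warming applied to every layer.
make_gradient_grid <- function(shift = 0, nrow = 10, ncol = 10) {
  g <- expand.grid(row = seq_len(nrow), col = seq_len(ncol))
  g$cell <- paste0("c", seq_len(nrow(g)))
  g$rain <- g$row * 10 + shift
  g$temp <- g$col * 2 + shift
  climate_grid(g[, c("cell", "row", "col", "rain", "temp")])
}

write_projection_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

# Fixed 3-taxon tree used in several worked examples.
tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")
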