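# fixture builders shared across test files; everything is generated in
# code so no binary data ships with the package

# volume with a single-voxel tumor and a single-voxel node at a known
# slice / in-plane offset (offsets in voxels; spacing converts to mm)
two_point_volume <- function(ds = 0L, row_off = 0L, col_off = 0L,
                             spacing = 0.5, thickness = 4, gap = 1,
                             dim = c(7L, 41L, 41L)) {
  v <- array(0L, dim)
  s0 <- 3L; r0 <- 11L; c0 <- 11L
  v[s0, r0, c0] <- 1L
  v[s0 + ds, r0 + row_off, c0 + col_off] <- 2L
  annotated_volume(v, spacing, slice_thickness = thickness,
                   slice_gap = gap, patient_id = "fixture")
}

# deterministic 50-row survival fixture with tied event times and one
# binary plus one continuous covariate; no RNG involved
survival_fixture_50 <- function() {
  i <- 1:50
  data.frame(
    time = rep(c(2, 3, 5, 5, 7, 11, 13, 13, 17, 19), 5) + (i %% 5),
    event = as.integer(i %% 3 != 0),
    x1 = as.numeric(i %% 2),
    x2 = round(sin(i) * 2, 3)
  )
}

# small cohort CSV written to a temp file
write_cohort_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}
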