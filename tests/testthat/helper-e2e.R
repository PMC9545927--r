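# Desk-scale end-to-end fixture: trains the tiny suppression and
# segmentation networks on blocks from four synthetic phantoms and runs
# the full pipeline on a held-out phantom. Built once per test run and
# shared by the acceptance assertions. Study conditions (grid, crops,
# epochs, training-length selection on a validation phantom) are
# documented in the methods vignette.

fix_e2e <- function() {
  memo("e2e", function() {
    p <- acq_params(fov_mm = 96 * 2.1, voxel_mm = 2.1)
    arm <- design_vd_arm(p, density_spec(), 1024)
    crop <- 64L; tcrop <- 48L; grid <- 96L
    y0 <- (grid - crop) %/% 2L; ys <- y0 + seq_len(crop)
    c0 <- (crop - tcrop) %/% 2L; cs <- c0 + seq_len(tcrop)
    mk_ph <- function(seed, hr, sv, dur)
      generate_phantom(phantom_config(grid = grid, duration_s = dur,
                                      hr_bpm = hr, sv_ml = sv,
                                      noise_sd = 0.01, n_coils = 3,
                                      seed = seed))
    pairs <- list(); seg_src <- list()
    for (tc in list(c(11, 65, 75), c(12, 80, 85),
                    c(13, 72, 90), c(14, 90, 70))) {
      ph <- mk_ph(tc[1], tc[2], tc[3], 4.2)
      acq <- simulate_acquisition(ph, p, arm, phi0 = 0, seed = 100 + tc[1])
      gs <- grid_series(acq, crop)
      enc_t <- cine_complex(ph$cine)[ys, ys, ]
      cmp_t <- (ph$cine$mag * (1 + 0i))[ys, ys, ]
      b_enc <- make_blocks(gs$enc, enc_t, 24, tcrop, paste0("ph", tc[1]))
      b_cmp <- make_blocks(gs$comp[, , 1:24], cmp_t[, , 1:24], 24, tcrop,
                           paste0("ph", tc[1], "c"))
      pairs <- c(pairs, b_enc, b_cmp)
      for (b in seq_along(b_enc)) {
        fr <- (b - 1L) * 24L + 1:24
        seg_src[[length(seg_src) + 1L]] <- list(
          comp = gs$comp[cs, cs, fr], enc = gs$enc[cs, cs, fr],
          mask = ph$truth$masks[ys, ys, fr][cs, cs, ],
          truth = enc_t[cs, cs, fr])
      }
    }
    sup <- train_suppressor(pairs, unet_spec(2, 8, 1, 1e-3), epochs = 8,
                            seed = 5, augment = TRUE)
    # segmentation trains on both clean and suppressor-restored
    # phase-contrast blocks, labels from the phantom masks
    mkpc <- function(s) {
      nb <- normalize_block(list(comp = s$comp, enc = s$enc,
                                 venc_cm_s = 200))
      rest <- suppress(sup, nb$pair)
      pc <- array(0 + 0i, dim = dim(rest$comp))
      for (j in 1:24)
        pc[, , j] <- combine_pair(list(comp = rest$comp[, , j],
                                       enc = rest$enc[, , j]))
      pc
    }
    seg_cases <- c(
      lapply(seg_src, function(s) list(input = seg_input(s$truth),
                                       mask = s$mask)),
      lapply(seg_src, function(s) list(input = seg_input(mkpc(s)),
                                       mask = s$mask)))
    seg <- train_segmenter(seg_cases, unet_spec(2, 8, 1, 2e-3), epochs = 12,
                           seed = 6)
    # held-out phantom, full pipeline
    ph_te <- mk_ph(99, 72, 80, 10.5)
    acq_te <- simulate_acquisition(ph_te, p, arm, phi0 = 0, seed = 42)
    gs_te <- grid_series(acq_te, crop)
    enc_te_t <- cine_complex(ph_te$cine)[ys, ys, ]
    blocks_te <- make_blocks(gs_te$enc, enc_te_t, 24, crop, "held")
    pipe <- run_pipeline(acq_te, sup, seg, crop = crop)
    list(p = p, arm = arm, crop = crop, ys = ys, sup = sup, seg = seg,
         pairs = pairs, ph_te = ph_te, blocks_te = blocks_te, pipe = pipe)
  })
}
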