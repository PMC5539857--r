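# Shared fixtures, built lazily and cached for the whole run.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = fixture_cache)) {
    assign(name, builder(), envir = fixture_cache)
  }
  get(name, envir = fixture_cache)
}

test_pulse <- function() cached("pulse", function() acoustic_pulse(48e6, 0.5, 400e6))

# speckle-free phantom: surface/interface echoes only, for exact-recovery work
specular_scan_set <- function() {
  cached("specular_ss", function() {
    ph <- gi_phantom(scatterer_density = 0, backscatter_strength = 0)
    generate_scan_set(
      scan_set_config(phantom = ph, noise_sd = 0, transmission = FALSE),
      seed = 101
    )
  })
}

# fully speckled default phantom, noiseless, transmission off
speckle_scan_set <- function() {
  cached("speckle_ss", function() {
    generate_scan_set(
      scan_set_config(noise_sd = 0, transmission = FALSE),
      seed = 102
    )
  })
}

# impedance-matched diffuse phantom: speckle only, no specular interfaces
diffuse_scan_set <- function(backscatter_strength, seed) {
  key <- sprintf("diffuse_%g_%d", backscatter_strength, seed)
  cached(key, function() {
    layers <- list(
      tissue_layer("mucosa", 1.5, 1.48, attenuation = 1.86,
        backscatter_strength = backscatter_strength, scatterer_density = 200
      ),
      tissue_layer("submucosa", 1.5, 1.48, attenuation = 1.86,
        backscatter_strength = backscatter_strength, scatterer_density = 200
      )
    )
    ph <- layered_phantom(layers, substrate_impedance = 1.48)
    generate_scan_set(
      scan_set_config(phantom = ph, noise_sd = 0, transmission = FALSE),
      seed = seed
    )
  })
}

# ground-truth tissue-band mask from the generator geometry (time-of-flight)
truth_band_mask <- function(ss) {
  scan <- ss$sample_scan
  ph <- ss$ground_truth
  fs <- scan$sampling_rate
  th <- vapply(ph$layers, `[[`, numeric(1), "thickness")
  cs <- vapply(ph$layers, `[[`, numeric(1), "sound_speed")
  t_top <- ph$standoff * 1e-3 / ph$coupling_sound_speed
  t_bot <- t_top + sum(th * 1e-3 / cs)
  i_top <- round(2 * t_top * fs) + 1L
  i_bot <- round(2 * t_bot * fs) + 1L
  truth <- matrix(FALSE, nrow(scan$rf), ncol(scan$rf))
  truth[, i_top:i_bot] <- TRUE
  truth
}

mask_iou <- function(a, b) sum(a & b) / sum(a | b)

# brute-force morphology oracle (infinite background), used to check closing
brute_dilate <- function(mask, kern) {
  kr <- (nrow(kern) - 1) / 2
  kc <- (ncol(kern) - 1) / 2
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      hit <- FALSE
      for (di in -kr:kr) {
        for (dj in -kc:kc) {
          if (kern[di + kr + 1, dj + kc + 1] == 0) next
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
              mask[ii, jj]) hit <- TRUE
        }
      }
      out[i, j] <- hit
    }
  }
  out
}

brute_erode <- function(mask, kern) {
  kr <- (nrow(kern) - 1) / 2
  kc <- (ncol(kern) - 1) / 2
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      ok <- TRUE
      for (di in -kr:kr) {
        for (dj in -kc:kc) {
          if (kern[di + kr + 1, dj + kc + 1] == 0) next
          ii <- i + di; jj <- j + dj
          inside <- ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask)
          # infinite background is FALSE, so any kernel cell off-grid fails
          if (!inside || !mask[ii, jj]) ok <- FALSE
        }
      }
      out[i, j] <- ok
    }
  }
  out
}

brute_close <- function(mask, kern) {
  # infinite-plane closing: pad so the dilation result is not clipped
  kr <- (nrow(kern) - 1) / 2
  kc <- (ncol(kern) - 1) / 2
  pad <- matrix(FALSE, nrow(mask) + 2 * kr, ncol(mask) + 2 * kc)
  pad[kr + seq_len(nrow(mask)), kc + seq_len(ncol(mask))] <- mask
  closed <- brute_erode(brute_dilate(pad, kern), kern)
  closed[kr + seq_len(nrow(mask)), kc + seq_len(ncol(mask)), drop = FALSE]
}

# brute-force flood-fill labelling oracle
brute_label <- function(mask, connectivity = 8) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  offs <- if (connectivity == 8) {
    expand.grid(di = -1:1, dj = -1:1)[-5, ]
  } else {
    data.frame(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
  }
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (!mask[i, j] || lab[i, j] > 0) next
      cur <- cur + 1L
      queue <- list(c(i, j))
      lab[i, j] <- cur
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(offs))) {
          ii <- p[1] + offs$di[k]; jj <- p[2] + offs$dj[k]
          if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            queue[[length(queue) + 1]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# minimal bscan wrapper for hand-built RF matrices
toy_bscan <- function(rf, sampling_rate = 100e6, line_pitch = 0.5,
                      sound_speed = 1540) {
  structure(
    list(
      rf = rf, sampling_rate = sampling_rate, line_pitch = line_pitch,
      scan_length = (nrow(rf) - 1) * line_pitch,
      sound_speed_assumed = sound_speed, depth_origin = 0
    ),
    class = "bscan"
  )
}

table3_fixture <- function() {
  readr::read_csv(
    system.file("extdata", "focused_transducer_outputs.csv", package = "qusim"),
    show_col_types = FALSE
  )
}
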