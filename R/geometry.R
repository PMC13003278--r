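# Core surface-area and volume descriptors for the five particle morphologies,
# plus a Monte-Carlo constructive-solid-geometry oracle used to validate the
# closed forms.
#
# Shape models:
#   sphere      - symmetric sphere of diameter d_TEM.
#   cube        - perfect cube with edge d_TEM.
#   nanoflower  - 13 identical tangent spheres (12 petals around one centre,
#                 icosahedral arrangement), sub-sphere radius d_TEM / 6. The
#                 area descriptor counts the 12 outer petals; the central
#                 sphere is internal to the cluster.
#   octahedron  - regular octahedron resting on a face; d_TEM is the projected
#                 height through the tilted adjacent face with external angle
#                 beta1, giving edge l = d / (sqrt(3/4) * (1 + cos(beta1))).
#   octopod     - central cube with a regular tetrahedron on each corner; the
#                 three base vertices of each tetrahedron sit on the midpoints
#                 of the three cube edges meeting at that corner, so the
#                 tetrahedron edge is l and the cube edge is sqrt(2) * l, with
#                 l = d / (1 + 2 * sqrt(3/4) * cos(beta2)). Exact union
#                 arithmetic (half of each tetrahedron's volume overlaps the
#                 cube corner; each corner hides three l^2/4 right triangles
#                 of cube face) gives
#                   A = 6 l^2 + 6 sqrt(3) l^2
#                   V = 2 sqrt(2) l^3 + 8 l^3 / (6 sqrt(2)) - 2 l^3 / (3 sqrt(2)).

SHAPES <- c("sphere", "cube", "nanoflower", "octahedron", "octopod")

# Default model angles: the inter-face geometry of a regular octahedron,
# cos(beta) = 1/3 (about 70.53 degrees). Exposed as configuration because the
# tilt of a particle resting on a substrate is a modelling assumption.
DEFAULT_BETA_DEG <- acos(1 / 3) * 180 / pi

#' Shape-model specification for core geometry
#'
#' @param shape One of `"sphere"`, `"cube"`, `"nanoflower"`, `"octahedron"`,
#'   `"octopod"`.
#' @param d_tem Mean core diameter from microscopy, nm; must be positive.
#' @param beta1 Octahedron tilt angle in degrees, in (0, 90); required for
#'   octahedra. Default `acos(1/3)` (~70.53 deg).
#' @param beta2 Octopod face angle in degrees, in (0, 90); required for
#'   octopods. Default `acos(1/3)`.
#' @return An object of class `geometry_spec`.
#' @export
geometry_spec <- function(shape, d_tem, beta1 = DEFAULT_BETA_DEG,
                          beta2 = DEFAULT_BETA_DEG) {
  shape <- match.arg(shape, SHAPES)
  if (!is_number(d_tem) || d_tem <= 0) stopf("d_tem must be a positive number")
  if (shape == "octahedron" && (!is_number(beta1) || beta1 <= 0 || beta1 >= 90)) {
    stopf("octahedron requires beta1 in (0, 90) degrees")
  }
  if (shape == "octopod" && (!is_number(beta2) || beta2 <= 0 || beta2 >= 90)) {
    stopf("octopod requires beta2 in (0, 90) degrees")
  }
  structure(list(shape = shape, d_tem = d_tem, beta1 = beta1, beta2 = beta2),
            class = "geometry_spec")
}

# Characteristic length of each model from d_TEM: sphere/cube use d directly;
# octahedron and octopod map the projected diameter to an edge length.
model_edge <- function(shape, d, beta1, beta2) {
  switch(shape,
    sphere = d,
    cube = d,
    nanoflower = d,
    octahedron = d / (sqrt(3 / 4) * (1 + cos(beta1 * pi / 180))),
    octopod = d / (1 + 2 * sqrt(3 / 4) * cos(beta2 * pi / 180))
  )
}

#' Core surface area and volume for a shape model
#'
#' Closed-form A_core (nm^2) and V_core (nm^3) under the five idealized solid
#' models described in the package vignette.
#'
#' @param spec A [geometry_spec()], or a shape name when `d_tem` is given.
#' @param d_tem,beta1,beta2 Convenience scalar/vector arguments used when
#'   `spec` is a shape name; `core_area_volume("sphere", d_tem = c(10, 20))`
#'   is vectorized over `d_tem`.
#' @return A list with numeric `A_core` and `V_core`.
#' @examples
#' core_area_volume(geometry_spec("sphere", 2))
#' core_area_volume("cube", d_tem = 1)
#' @export
core_area_volume <- function(spec, d_tem = NULL, beta1 = DEFAULT_BETA_DEG,
                             beta2 = DEFAULT_BETA_DEG) {
  if (inherits(spec, "geometry_spec")) {
    shape <- spec$shape
    d <- spec$d_tem
    beta1 <- spec$beta1
    beta2 <- spec$beta2
  } else {
    shape <- match.arg(spec, SHAPES)
    if (is.null(d_tem)) stopf("d_tem is required when spec is a shape name")
    d <- d_tem
  }
  if (any(d <= 0)) stopf("d_tem must be positive")
  l <- model_edge(shape, d, beta1, beta2)
  out <- switch(shape,
    sphere = list(A_core = 4 * pi * (d / 2)^2,
                  V_core = (4 / 3) * pi * (d / 2)^3),
    cube = list(A_core = 6 * d^2, V_core = d^3),
    nanoflower = {
      r <- d / 6
      list(A_core = 12 * 4 * pi * r^2, V_core = 13 * (4 / 3) * pi * r^3)
    },
    octahedron = list(A_core = 2 * sqrt(3) * l^2,
                      V_core = (sqrt(2) / 3) * l^3),
    octopod = list(
      A_core = 6 * l^2 + 6 * sqrt(3) * l^2,
      V_core = 2 * sqrt(2) * l^3 + 8 * l^3 / (6 * sqrt(2)) - 2 * l^3 / (3 * sqrt(2))
    )
  )
  out
}

#' Surface-to-volume ratio
#'
#' @param A Surface area, nm^2.
#' @param V Volume, nm^3; must be positive.
#' @return A / V in 1/nm.
#' @export
av_ratio <- function(A, V) {
  if (any(V <= 0)) stopf("V must be positive")
  A / V
}

# ---- Monte-Carlo geometry oracle -------------------------------------------

# Icosahedron vertex directions (unit vectors), used for the nanoflower petal
# centres at distance 2r from the cluster centre (tangent, non-overlapping).
icosahedron_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(phi, 0, -1), c(-phi, 0, 1), c(-phi, 0, -1)
  )
  v / sqrt(1 + phi^2)
}

# Vertices of the octopod's 8 corner tetrahedra for a cube of edge s centred
# at the origin. Rows: base vertices m1..m3 (cube edge midpoints), apex.
octopod_tetrahedra <- function(s) {
  signs <- as.matrix(expand.grid(sx = c(-1, 1), sy = c(-1, 1), sz = c(-1, 1)))
  lapply(seq_len(nrow(signs)), function(i) {
    sg <- signs[i, ]
    rbind(
      c(0, sg[2] * s / 2, sg[3] * s / 2),
      c(sg[1] * s / 2, 0, sg[3] * s / 2),
      c(sg[1] * s / 2, sg[2] * s / 2, 0),
      (2 * s / 3) * sg
    )
  })
}

# Membership of points (n x 3 matrix) in a tetrahedron given 4 x 3 vertices,
# via barycentric coordinates. `margin` < 0 shrinks to the strict interior.
points_in_tetrahedron <- function(p, verts, margin = 0) {
  m <- t(verts[1:3, , drop = FALSE]) - verts[4, ]
  b <- solve(m, t(p) - verts[4, ])
  ok <- b[1, ] >= margin & b[2, ] >= margin & b[3, ] >= margin &
    (1 - colSums(b)) >= margin
  ok
}

# Membership predicate for the full solid of a geometry spec. Returns a
# function(p) -> logical over rows of p, plus the half-width of a bounding box.
solid_membership <- function(spec) {
  d <- spec$d_tem
  shape <- spec$shape
  l <- model_edge(shape, d, spec$beta1, spec$beta2)
  switch(shape,
    sphere = list(
      contains = function(p) rowSums(p^2) <= (d / 2)^2,
      half_width = d / 2
    ),
    cube = list(
      contains = function(p) {
        apply(abs(p) <= d / 2, 1, all)
      },
      half_width = d / 2
    ),
    nanoflower = {
      r <- d / 6
      centers <- rbind(c(0, 0, 0), 2 * r * icosahedron_vertices())
      list(
        contains = function(p) {
          inside <- rep(FALSE, nrow(p))
          for (i in seq_len(nrow(centers))) {
            di <- sweep(p, 2, centers[i, ])
            inside <- inside | rowSums(di^2) <= r^2
          }
          inside
        },
        half_width = 3 * r
      )
    },
    octahedron = {
      s <- l / sqrt(2) # vertex distance from centre
      list(
        contains = function(p) rowSums(abs(p)) <= s,
        half_width = s
      )
    },
    octopod = {
      s <- sqrt(2) * l
      tets <- octopod_tetrahedra(s)
      list(
        contains = function(p) {
          inside <- rowSums(abs(p) <= s / 2) == 3L
          for (tet in tets) inside <- inside | points_in_tetrahedron(p, tet)
          inside
        },
        half_width = 2 * s / 3
      )
    }
  )
}

# Surface primitives of a solid: list of faces, each with an exact area, a
# sampler of uniform points on the face, and the index of the owning
# primitive (points are tested against all *other* primitives' interiors).
surface_primitives <- function(spec) {
  d <- spec$d_tem
  shape <- spec$shape
  l <- model_edge(shape, d, spec$beta1, spec$beta2)
  sphere_face <- function(center, r, owner) {
    list(
      area = 4 * pi * r^2,
      sample = function(n) {
        g <- matrix(stats::rnorm(3 * n), ncol = 3)
        g <- g / sqrt(rowSums(g^2))
        sweep(r * g, 2, center, "+")
      },
      owner = owner
    )
  }
  tri_face <- function(v1, v2, v3, owner) {
    e1 <- v2 - v1
    e2 <- v3 - v1
    area <- 0.5 * sqrt(sum(crossprod3(e1, e2)^2))
    list(
      area = area,
      sample = function(n) {
        u <- sqrt(stats::runif(n))
        v <- stats::runif(n)
        outer(1 - u, v1) + outer(u * (1 - v), v2) + outer(u * v, v3)
      },
      owner = owner
    )
  }
  square_face <- function(center, ax1, ax2, half, owner) {
    list(
      area = (2 * half)^2,
      sample = function(n) {
        u <- stats::runif(n, -half, half)
        v <- stats::runif(n, -half, half)
        sweep(outer(u, ax1) + outer(v, ax2), 2, center, "+")
      },
      owner = owner
    )
  }
  cube_faces <- function(s, owner) {
    axes <- diag(3)
    out <- list()
    for (k in 1:3) {
      for (sg in c(-1, 1)) {
        others <- setdiff(1:3, k)
        out[[length(out) + 1L]] <- square_face(
          sg * (s / 2) * axes[k, ], axes[others[1], ], axes[others[2], ],
          s / 2, owner
        )
      }
    }
    out
  }
  switch(shape,
    sphere = list(
      faces = list(sphere_face(c(0, 0, 0), d / 2, 1L)),
      interiors = list()
    ),
    cube = list(
      faces = cube_faces(d, 1L),
      interiors = list()
    ),
    nanoflower = {
      # Area model: the 12 outer petals; each petal tested against the other
      # petals (tangency means nothing is occluded in exact arithmetic).
      r <- d / 6
      centers <- 2 * r * icosahedron_vertices()
      faces <- lapply(seq_len(nrow(centers)), function(i) {
        sphere_face(centers[i, ], r, i)
      })
      interiors <- lapply(seq_len(nrow(centers)), function(i) {
        force(i)
        function(p) {
          di <- sweep(p, 2, centers[i, ])
          rowSums(di^2) < r^2 * (1 - 1e-12)
        }
      })
      list(faces = faces, interiors = interiors)
    },
    octahedron = {
      s <- l / sqrt(2)
      verts <- rbind(
        c(s, 0, 0), c(-s, 0, 0), c(0, s, 0), c(0, -s, 0), c(0, 0, s), c(0, 0, -s)
      )
      combos <- expand.grid(x = c(1, 2), y = c(3, 4), z = c(5, 6))
      faces <- lapply(seq_len(nrow(combos)), function(i) {
        tri_face(verts[combos$x[i], ], verts[combos$y[i], ], verts[combos$z[i], ], 1L)
      })
      list(faces = faces, interiors = list())
    },
    octopod = {
      s <- sqrt(2) * l
      tets <- octopod_tetrahedra(s)
      faces <- cube_faces(s, 1L)
      for (i in seq_along(tets)) {
        tet <- tets[[i]]
        cmb <- utils::combn(4, 3)
        for (j in seq_len(ncol(cmb))) {
          faces[[length(faces) + 1L]] <-
            tri_face(tet[cmb[1, j], ], tet[cmb[2, j], ], tet[cmb[3, j], ], 1L + i)
        }
      }
      interiors <- c(
        list(function(p) apply(abs(p) < s / 2 * (1 - 1e-12), 1, all)),
        lapply(tets, function(tet) {
          force(tet)
          function(p) points_in_tetrahedron(p, tet, margin = 1e-12)
        })
      )
      list(faces = faces, interiors = interiors)
    }
  )
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Monte-Carlo oracle for core area and volume
#'
#' Independent sampling-based estimates of the solid models' surface area and
#' volume, used to validate the closed forms in [core_area_volume()]. Volume
#' is estimated by point-membership sampling in a bounding box; area by
#' surface sampling of the constituent primitives with occlusion testing
#' against the other primitives' interiors (exact primitive areas, estimated
#' exposed fractions). Both estimates carry Monte-Carlo standard errors.
#'
#' @param spec A [geometry_spec()].
#' @param n_points Number of sample points (at least 1e4).
#' @param seed Integer RNG seed.
#' @return A list with `A_est`, `A_se`, `V_est`, `V_se`.
#' @export
mc_area_volume_oracle <- function(spec, n_points = 1e6, seed = 1) {
  stopifnot(inherits(spec, "geometry_spec"))
  if (n_points < 1e4) stopf("n_points must be at least 1e4")
  with_seed(seed, {
    solid <- solid_membership(spec)
    hw <- solid$half_width
    box_vol <- (2 * hw)^3
    # volume: sample in chunks to bound memory
    n_left <- n_points
    hits <- 0
    while (n_left > 0) {
      m <- min(n_left, 250000L)
      p <- matrix(stats::runif(3 * m, -hw, hw), ncol = 3)
      hits <- hits + sum(solid$contains(p))
      n_left <- n_left - m
    }
    phat <- hits / n_points
    v_est <- box_vol * phat
    v_se <- box_vol * sqrt(phat * (1 - phat) / n_points)

    surf <- surface_primitives(spec)
    n_faces <- length(surf$faces)
    per_face <- ceiling(n_points / n_faces)
    a_est <- 0
    a_var <- 0
    for (i in seq_len(n_faces)) {
      face <- surf$faces[[i]]
      p <- face$sample(per_face)
      exposed <- rep(TRUE, nrow(p))
      for (j in seq_along(surf$interiors)) {
        if (j == face$owner) next
        exposed <- exposed & !surf$interiors[[j]](p)
      }
      fr <- mean(exposed)
      a_est <- a_est + face$area * fr
      a_var <- a_var + face$area^2 * fr * (1 - fr) / per_face
    }
    list(A_est = a_est, A_se = sqrt(a_var), V_est = v_est, V_se = v_se)
  })
}
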