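# Internal articulated skeleton used by the synthetic stimulus generator.
#
# 22 labeled keypoints on a macaque-like kinematic tree. Labels are
# placeholders: downstream analyses depend only on the count and the tree
# structure, never on anatomical identity.

kp_labels <- c(
  "nose", "chin", "head_top", "neck",
  "l_shoulder", "r_shoulder", "l_elbow", "r_elbow", "l_hand", "r_hand",
  "mid_spine", "lower_back", "pelvis",
  "l_hip", "r_hip", "l_knee", "r_knee", "l_foot", "r_foot",
  "tail_base", "tail_mid", "tail_tip"
)

# parent -> child edges; ordered so every parent precedes its children.
kp_bones <- function() {
  e <- rbind(
    c("pelvis", "lower_back"),
    c("lower_back", "mid_spine"),
    c("mid_spine", "neck"),
    c("neck", "head_top"),
    c("head_top", "nose"),
    c("nose", "chin"),
    c("neck", "l_shoulder"),
    c("neck", "r_shoulder"),
    c("l_shoulder", "l_elbow"),
    c("r_shoulder", "r_elbow"),
    c("l_elbow", "l_hand"),
    c("r_elbow", "r_hand"),
    c("pelvis", "l_hip"),
    c("pelvis", "r_hip"),
    c("l_hip", "l_knee"),
    c("r_hip", "r_knee"),
    c("l_knee", "l_foot"),
    c("r_knee", "r_foot"),
    c("pelvis", "tail_base"),
    c("tail_base", "tail_mid"),
    c("tail_mid", "tail_tip")
  )
  matrix(match(e, kp_labels), ncol = 2,
         dimnames = list(NULL, c("parent", "child")))
}

# Bone lengths in model units (body scale ~ 1).
kp_bone_lengths <- c(
  0.50, 0.50, 0.50,         # spine
  0.35, 0.25, 0.15,         # head chain
  0.30, 0.30,               # shoulders
  0.45, 0.45, 0.45, 0.45,   # arms
  0.25, 0.25,               # hips
  0.50, 0.50, 0.50, 0.50,   # legs
  0.40, 0.35, 0.30          # tail
)

# Neutral quadruped-ish direction (azimuth about vertical axis, elevation)
# per bone, radians. Azimuth 0 points along +z (toward the default camera);
# the body axis runs along x.
kp_neutral_angles <- function() {
  hp <- pi / 2
  rbind(
    c(-hp, 0.35),  # pelvis -> lower_back (toward head, slightly up)
    c(-hp, 0.10),
    c(-hp, 0.25),
    c(-hp, 1.10),  # neck -> head_top
    c(-hp, 0.10),  # head_top -> nose
    c(-hp, -1.20), # nose -> chin
    c(0, -0.9),    # neck -> l_shoulder (left = +z side)
    c(pi, -0.9),   # neck -> r_shoulder
    c(0.3, -1.2),  # l_shoulder -> l_elbow
    c(pi - 0.3, -1.2),
    c(-0.3, -1.2), # elbows -> hands
    c(pi + 0.3, -1.2),
    c(0.2, -1.0),  # pelvis -> l_hip
    c(pi - 0.2, -1.0),
    c(0.3, -1.1),  # hips -> knees
    c(pi - 0.3, -1.1),
    c(-0.2, -1.2), # knees -> feet
    c(pi + 0.2, -1.2),
    c(hp, 0.5),    # pelvis -> tail_base (away from head, up)
    c(hp, 0.9),
    c(hp, 1.1)
  )
}

# Forward kinematics: angles (n_bones x 2: azimuth, elevation) -> 22 x 3
# model-space coordinates, y up, pelvis at the origin.
kp_forward <- function(angles) {
  bones <- kp_bones()
  len <- kp_bone_lengths
  coords <- matrix(NA_real_, length(kp_labels), 3)
  coords[match("pelvis", kp_labels), ] <- 0
  for (b in seq_len(nrow(bones))) {
    phi <- angles[b, 1]
    psi <- angles[b, 2]
    dir <- c(cos(psi) * sin(phi), sin(psi), cos(psi) * cos(phi))
    coords[bones[b, 2], ] <- coords[bones[b, 1], ] + len[b] * dir
  }
  coords
}

# Camera-aligned orthographic projection of one pose.
#
# The skeleton (22 x 3 model coordinates, y up) is centered on the pelvis,
# rotated about its vertical axis by `azimuth`, then the camera elevation is
# applied; `hanging = TRUE` replicates the special handling of hanging poses
# (camera displaced downward, looking up with the same tilt). Returns 22 x 3:
# image-plane x, image-plane y (increasing downward), and z = signed distance
# from the frontal plane — all still in model units (no global scaling).
project_pose <- function(coords, azimuth, elevation, hanging = FALSE) {
  pelvis <- coords[match("pelvis", kp_labels), ]
  centered <- sweep(coords, 2, pelvis)
  tilt <- if (hanging) -elevation else elevation
  cam <- t(rot_x(tilt) %*% rot_y(azimuth) %*% t(centered))
  cbind(x = cam[, 1], y = -cam[, 2], z = cam[, 3])
}

# Draw per-class joint-angle distributions and per-pose exemplar angles.
# Classes are mutually distinguishable by construction (distinct mean angle
# offsets); exemplars jitter around the class mean. One designated class is
# flagged "hanging".
sample_pose_angles <- function(n_poses, n_classes = 9, exemplar_sd = 0.12,
                               class_spread = 0.55) {
  n_bones <- nrow(kp_bones())
  neutral <- kp_neutral_angles()
  n_classes <- min(n_classes, n_poses)
  per_class <- ceiling(n_poses / n_classes)
  class_offsets <- lapply(seq_len(n_classes), function(cl) {
    matrix(stats::runif(n_bones * 2, -class_spread, class_spread),
           n_bones, 2)
  })
  poses <- vector("list", n_poses)
  pose_class <- integer(n_poses)
  for (p in seq_len(n_poses)) {
    cl <- (p - 1) %/% per_class + 1L
    pose_class[p] <- cl
    jitter <- matrix(stats::rnorm(n_bones * 2, 0, exemplar_sd), n_bones, 2)
    ang <- neutral + class_offsets[[cl]] + jitter
    # hanging class: body flipped upside down (limbs point up)
    if (cl == n_classes && n_classes > 1) ang[, 2] <- -ang[, 2]
    poses[[p]] <- ang
  }
  list(angles = poses, pose_class = pose_class,
       hanging_class = if (n_classes > 1) n_classes else -1L)
}
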