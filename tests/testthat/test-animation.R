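## a scene that renders instantly: no atlas, one tiny glyph
tinyScene <- function() {
  sc <- brainScene(NULL, addRoot = FALSE)
  addActor(sc, makeActor(icosphere(0L), name = "ball"))
}

test_that("keyframes stay sorted and reject duplicates", {
  anim <- sceneAnimation(tinyScene(), fps = 10)
  cam <- cameraPose(c(0, 0, 0), c(1, 0, 0))
  anim <- addKeyframe(anim, 0, camera = cam)
  anim <- addKeyframe(anim, 2, camera = cam)
  anim <- addKeyframe(anim, 1, camera = cam)
  tms <- vapply(anim@keyframes, function(k) k@time, numeric(1))
  expect_equal(tms, c(0, 1, 2))
  expect_error(addKeyframe(anim, 1), "duplicate keyframe")
  expect_error(addKeyframe(anim, 5, actorParams = list(ghost = list(
    alpha = 1))), "nearest matches")
})

test_that("stateAt interpolates linearly and hits keyframes exactly", {
  sc <- tinyScene()
  anim <- sceneAnimation(sc, fps = 10)
  anim <- addKeyframe(anim, 0,
                      camera = cameraPose(c(0, 0, 0), c(100, 0, 0),
                                          zoom = 1),
                      actorParams = list(ball = list(alpha = 1.0)))
  anim <- addKeyframe(anim, 2,
                      camera = cameraPose(c(10, 0, 0), c(100, 0, 0),
                                          zoom = 3))
  anim <- addKeyframe(anim, 3,
                      actorParams = list(ball = list(alpha = 0.0)))
  mid <- stateAt(anim, 1)
  expect_equal(mid$camera@position, c(5, 0, 0))
  expect_equal(mid$camera@zoom, 2)
  ## at a keyframe time the keyed values are exact
  expect_equal(stateAt(anim, 2)$camera@position, c(10, 0, 0))
  expect_equal(stateAt(anim, 0)$actorParams$ball$alpha, 1.0)
  expect_equal(stateAt(anim, 3)$actorParams$ball$alpha, 0.0)
  ## alpha keyed at 0 and 3: linear in between
  expect_equal(stateAt(anim, 1.5)$actorParams$ball$alpha, 0.5)
  ## camera has no keyframe after t=2: held
  expect_equal(stateAt(anim, 2.5)$camera@position, c(10, 0, 0))
  expect_error(stateAt(anim, 5), "outside keyframe range")
})

test_that("stateAt is numerically continuous in time", {
  anim <- sceneAnimation(tinyScene(), fps = 10)
  anim <- addKeyframe(anim, 0,
                      camera = cameraPose(c(0, 0, 0), c(100, 0, 0)),
                      actorParams = list(ball = list(alpha = 0.2)))
  anim <- addKeyframe(anim, 1,
                      camera = cameraPose(c(40, 10, -5), c(100, 0, 0)),
                      actorParams = list(ball = list(alpha = 0.9)))
  eps <- 1e-7
  for (t in c(0.25, 0.5, 1 - 2 * eps)) {
    s1 <- stateAt(anim, t)
    s2 <- stateAt(anim, t + eps)
    expect_lt(max(abs(s1$camera@position - s2$camera@position)), 1e-4)
    expect_lt(abs(s1$actorParams$ball$alpha - s2$actorParams$ball$alpha),
              1e-4)
  }
})

test_that("frame counts follow the half-open time grid", {
  set.seed(81)
  sc <- brainScene(NULL, addRoot = FALSE)  # empty scene: fast frames
  for (i in 1:20) {
    fps <- sample(1:10, 1)
    nWant <- sample(2:20, 1)
    duration <- nWant / fps
    anim <- sceneAnimation(sc, fps = fps)
    anim <- addKeyframe(anim, 0, camera = cameraPose(c(0, 0, 0),
                                                     c(1, 0, 0)))
    anim <- addKeyframe(anim, duration,
                        camera = cameraPose(c(1, 1, 0), c(1, 0, 0)))
    d <- tempfile("frames")
    frames <- writeFrames(anim, d, width = 16L, height = 12L)
    expect_length(frames, nWant)
    expect_true(all(file.exists(frames)))
    unlink(d, recursive = TRUE)
  }
})

test_that("low-rate animations land frames on the grid times", {
  sc <- tinyScene()
  anim <- sceneAnimation(sc, fps = 1)
  anim <- addKeyframe(anim, 0, camera = cameraPose(c(0, 0, 5), c(1, 0, 0)))
  anim <- addKeyframe(anim, 2, camera = cameraPose(c(2, 0, 5), c(1, 0, 0)))
  d <- tempfile("frames")
  frames <- writeFrames(anim, d, width = 16L, height = 12L)
  expect_length(frames, 2L)  # t = 0 and t = 1
  expect_equal(basename(frames), c("frame_00000.png", "frame_00001.png"))
  imgs <- lapply(frames, png::readPNG)
  expect_equal(dim(imgs[[1]]), dim(imgs[[2]]))
  expect_error(writeFrames(sceneAnimation(sc), tempfile()),
               "at least 2 keyframes")
})
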