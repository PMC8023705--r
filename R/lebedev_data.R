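# Generated by data-raw/lebedev-solve.R -- do not edit by hand.
# Orbit parameters and weights of the Lebedev-type angular grids,
# solved from the spherical moment equations and frozen here.
.lebedev_params <- list(
  `6` = list(degree = 3,
    orbits = list(
      list(type = "a1", w = 0.16666666666666671))),
  `14` = list(degree = 5,
    orbits = list(
      list(type = "a1", w = 0.06666666666666668),
      list(type = "a3", w = 0.074999999999999997))),
  `26` = list(degree = 7,
    orbits = list(
      list(type = "a1", w = 0.04761904761904763),
      list(type = "a2", w = 0.038095238095238133),
      list(type = "a3", w = 0.032142857142857084))),
  `38` = list(degree = 9,
    orbits = list(
      list(type = "a1", w = 0.0095238095238095698),
      list(type = "a3", w = 0.032142857142857112),
      list(type = "c", w = 0.028571428571428567, a = 0.88807383397711515))),
  `50` = list(degree = 11,
    orbits = list(
      list(type = "a1", w = 0.012698412698412749),
      list(type = "a2", w = 0.022574955908289267),
      list(type = "a3", w = 0.021093749999999977),
      list(type = "b", w = 0.020173335537918856, a = 0.30151134457776374))),
  `86` = list(degree = 15,
    orbits = list(
      list(type = "a1", w = 0.011544011544011587),
      list(type = "a3", w = 0.011943909085856337),
      list(type = "b", w = 0.011876501294537345, a = 0.69435400660266577),
      list(type = "b", w = 0.011110555710603239, a = 0.36960284645414715),
      list(type = "c", w = 0.011812303746904408, a = 0.37424303909034201))),
  `110` = list(degree = 17,
    orbits = list(
      list(type = "a1", w = 0.0038282704949507531),
      list(type = "a3", w = 0.009793737512483568),
      list(type = "b", w = 0.0095954713360692848, a = 0.395689473055999),
      list(type = "b", w = 0.0099428148911774126, a = 0.69042104838229323),
      list(type = "b", w = 0.0082117372831912866, a = 0.18511563534483344),
      list(type = "c", w = 0.0096949963616631343, a = 0.47836902881215437))),
  `146` = list(degree = 19,
    orbits = list(
      list(type = "a1", w = 0.00059963136877548551),
      list(type = "a2", w = 0.007372999718655189),
      list(type = "a3", w = 0.0072105153601133565),
      list(type = "b", w = 0.0067538294862871367, a = 0.41749612279677961),
      list(type = "b", w = 0.0075743941590587201, a = 0.15746766720338853),
      list(type = "b", w = 0.0071163554931114705, a = 0.67644104001128902),
      list(type = "d", w = 0.0069910873533250437, a = 0.14035538117183483, b = 0.44933283232675403))),
  `170` = list(degree = 21,
    orbits = list(
      list(type = "a1", w = 0.0055448429025409971),
      list(type = "a2", w = 0.0060713327707457567),
      list(type = "a3", w = 0.0063836747737236674),
      list(type = "b", w = 0.0062016700066309591, a = 0.43189106966645974),
      list(type = "b", w = 0.0051833875877385213, a = 0.2551252621031031),
      list(type = "b", w = 0.0063179290098545407, a = 0.6743601460353853),
      list(type = "c", w = 0.0054771433848808636, a = 0.26139313604155801),
      list(type = "d", w = 0.0059683839876562162, a = 0.8544158046839101, b = 0.49904531618066977))),
  `194` = list(degree = 23,
    orbits = list(
      list(type = "a1", w = 0.0017823269987803471),
      list(type = "a2", w = 0.0057169061101567612),
      list(type = "a3", w = 0.0055733845488392785),
      list(type = "b", w = 0.0055187724412377572, a = 0.44469329005531266),
      list(type = "b", w = 0.0051582390505925573, a = 0.28924649315626105),
      list(type = "b", w = 0.0056087044371489021, a = 0.67129734409630992),
      list(type = "b", w = 0.0041067772542850286, a = 0.1299334148555657),
      list(type = "c", w = 0.0050518458766363869, a = 0.34577020798340063),
      list(type = "d", w = 0.0055302489761897434, a = 0.15904170641801835, b = 0.52511856618313812)))
)
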