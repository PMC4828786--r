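# Reference mechanical properties of PolyJet TangoPlus/VeroWhite rubber-like
# composites from bench compliance tests on printed thin-walled cylinders
# (d = 20 mm, l = 60 mm, t = 0.8 mm unless noted; T50 tested at t = 1.2 mm,
# d = 14.6 mm).  D = distensibility (1/mmHg), E = Young's modulus (MPa).
# source = "measured": endpoint values reported for the tested series
#   (T100: D = 0.0060, E = 0.55; T75: D = 0.0024, E = 1.62; T50 at 1.2 mm:
#   D = 0.00025, E = 13.19 from uniaxial tensile test).
# source = "synthetic": interpolated placeholders for the intermediate mixes
#   (the series endpoints bracket them); shipped only so the monotone
#   composition trend (stiffer mix -> higher E, lower D) can be asserted.
name,pct_tango,pct_vero,thickness_mm,D_per_mmHg,E_MPa,source
T100,100,0,0.8,0.0060,0.55,measured
T92,92,8,0.8,0.0047,0.79,synthetic
T83,83,17,0.8,0.0035,1.15,synthetic
T75,75,25,0.8,0.0024,1.62,measured
T50,50,50,1.2,0.00025,13.19,measured
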