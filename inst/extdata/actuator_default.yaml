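# Default configuration of the 50 mm-stroke pneumatic compression
# actuator (SI units). 40 mm bore double-acting cylinder fed
# at 0.45 MPa absolute through a voltage-controlled electro-pneumatic
# regulator; chest block is the adult sternal spring-damper model.
gas:
  R: 287.05        # specific gas constant, J/(kg K)
  k: 1.4           # adiabatic index
  c0: 0.9          # throttle flow coefficient
regulator:
  tau_v: 0.005     # spool response time, s
  k_v: 1.0e-3      # spool displacement gain, m/V
  w: 6.0e-4        # area gain, m^2 per m of spool travel
cylinder:
  A1: 1.2566e-3    # rodless-side piston area, m^2
  A2: 7.0e-4       # rod-side piston area, m^2
  L: 0.05          # stroke, m
  X10: 0.005       # rodless dead-volume equivalent length, m
  X20: 0.005       # rod-side dead-volume equivalent length, m
  M_W: 1.5         # moving mass, kg
  F1: 40.0         # Coulomb friction, N
  F3: 14.7         # gravity component along the motion, N
  Ps: 4.5e+5        # supply pressure (absolute), Pa
  Ts: 293.15       # supply temperature, K
  Pa: 1.01325e+5    # ambient pressure, Pa
  Ta: 293.15       # ambient temperature, K
  A_exh1: 3.0e-6   # rodless-side valve exhaust-path effective area, m^2
  A_exh2: 4.0e-6   # rod-side valve exhaust-path effective area, m^2
chest:
  k1: 7028.9       # sternal spring elasticity, N/m
  m: 438.1         # sternal damping factor, N s/m
pid:
  kp: 1000.0       # V/m
  ki: 100.0        # V/(m s)
  kd: 18.0         # V s/m
  u_max: 5.0       # saturation voltage, V
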