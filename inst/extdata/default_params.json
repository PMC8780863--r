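{
  "v_dark": 0.260757698689966,
  "v_light": 2.91453936216068,
  "K_I": 0.536490199299213,
  "h": 3.40971093799268,
  "d_M": 0.23215477157647,
  "k_s": 0.585416198210714,
  "tau": 5.30869354863077,
  "d_F": 0.440347596593353,
  "v_w": 0.110471573834938,
  "k_fw": 0.0318243087617573,
  "d_Mw": 0.299909991376989,
  "k_w": 0.233979891628676,
  "d_Wd": 0.0305781272625175,
  "d_Wl": 1.29429266282399,
  "k_act": 3.50184318727335,
  "k_rel": 0.699311031817411,
  "K_V": 0.967441351847225,
  "k_v": 0.00525304051439291,
  "d_V": 2.80732586939169,
  "frq_null": false,
  "wc_null": false,
  "vvd_null": false
}
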