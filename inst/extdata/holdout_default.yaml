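aport:
  test:
  - 25.0
  - 45.0
  val:
  - 65.0
  - 30.0
gala:
  test:
  - 40.0
  - 60.0
  val:
  - 25.0
  - 45.0
golden:
  test:
  - 55.0
  - 75.0
  val:
  - 40.0
  - 60.0
granny_smith:
  test:
  - 70.0
  - 35.0
  val:
  - 55.0
  - 75.0
idared:
  test:
  - 30.0
  - 50.0
  val: 70.0
prince:
  test:
  - 45.0
  - 65.0
  val: 30.0
simirenko:
  test: 60.0
  val: 25.0
starcrimson:
  test: 75.0
  val: 40.0
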