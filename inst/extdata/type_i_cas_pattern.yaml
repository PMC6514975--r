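# "CAS" character pattern rendered at the retina with the 512-element array.
array: type_i
target:
  bitmap: cas_bitmap.txt   # resolved relative to this file
  bitmap_pitch: 1
  z: -12
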