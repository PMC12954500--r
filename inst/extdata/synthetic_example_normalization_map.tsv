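# normalisation map for the bundled synthetic example records
# field<TAB>raw<TAB>canonical
body_part	ankle	Ankle
body_part	foot	Foot
body_part	hip and groin	Hip and Groin
body_part	knee	Knee
body_part	lower leg	Lower Leg
body_part	shoulder	Shoulder
body_part	thigh	Thigh
body_part	trunk	Trunk
body_part	ANKLE	Ankle
body_part	FOOT	Foot
body_part	HIP AND GROIN	Hip and Groin
body_part	KNEE	Knee
body_part	LOWER LEG	Lower Leg
body_part	SHOULDER	Shoulder
body_part	THIGH	Thigh
body_part	TRUNK	Trunk
nature	joint	joint
nature	ligament	ligament
nature	tendon	tendon
nature	muscle	muscle
nature	JOINT	joint
nature	LIGAMENT	ligament
nature	TENDON	tendon
nature	MUSCLE	muscle
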