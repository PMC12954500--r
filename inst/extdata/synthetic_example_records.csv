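player_id,injury_date,season_label,body_part,side,nature,category,onset,severity_days,contact,context,recurrence_class
P0001,2016-01-03,2015-16,Thigh,left,muscle,Hamstring Muscle Injury,sudden,1,no,not_applicable,index
P0001,2016-04-28,2015-16,Thigh,left,muscle,Hamstring Muscle Injury,sudden,3,no,training,reinjury
P0001,2016-10-30,2016-17,Knee,left,ligament,ACL,sudden,14,no,training,index
P0001,2016-12-15,2016-17,Thigh,right,muscle,Hamstring Muscle Injury,sudden,3,no,training,index
P0002,2016-07-20,2016-17,Ankle,right,ligament,Ankle Sprain,sudden,4,no,match,index
P0003,2015-09-23,2015-16,Shoulder,right,joint,Shoulder Joint Injury,sudden,2,no,not_applicable,index
P0003,2015-10-31,2015-16,shoulder,right,joint,Shoulder Joint Injury,sudden,16,no,match,reinjury
P0003,2016-04-29,2015-16,Knee,right,joint,Knee Joint Injury,gradual,28,no,match,index
,2016-07-18,2016-17,Thigh,left,muscle,Hamstring Muscle Injury,sudden,4,no,match,index
P0003,2017-02-14,2016-17,Ankle,left,joint,Ankle Joint Injury,gradual,11,no,not_applicable,index
P0003,2017-02-20,2016-17,Thigh,left,tendon,Hamstring Tendon Injury,gradual,2,no,not_applicable,index
P0003,2017-03-11,2016-17,Lower Leg,right,tendon,Achilles Tendinopathy,sudden,14,no,match,index
P0005,2016-10-22,2016-17,Knee,right,ligament,ACL,sudden,2,no,match,index
P0006,2015-07-08,2015-16,Thigh,left,muscle,Hamstring Muscle Injury,sudden,10,no,match,index
P0006,2016-02-13,2015-16,Knee,right,ligament,ACL,sudden,36,no,training,index
P0006,2016-09-30,2016-17,Knee,left,ligament,ACL,sudden,26,no,training,index
P0006,2017-01-09,2016-17,Knee,left,joint,Knee Joint Injury,sudden,6,no,match,index
P0007,2016-10-04,2016-17,Ankle,right,ligament,Ankle Sprain,gradual,5,no,training,index
P0007,2017-01-21,2016-17,Ankle,right,ligament,Ankle Sprain,sudden,17,no,training,reinjury
P0008,2016-12-06,2016-17,Thigh,left,muscle,Hamstring Muscle Injury,sudden,9,no,match,index
P0010,2016-10-27,2016-17,Hip and Groin,left,muscle,Groin Muscle Injury,gradual,18,no,training,index
P0010,2017-01-15,2016-17,Hip and Groin,left,tendon,Groin Tendon Injury,sudden,12,no,match,index
P0011,2015-10-24,2015-16,Thigh,left,muscle,Hamstring Muscle Injury,gradual,2,no,training,index
P0012,2015-12-08,2015-16,Lower Leg,left,tendon,Achilles Tendinopathy,gradual,14,no,training,index
P0014,2015-07-06,2015-16,Thigh,left,muscle,Hamstring Muscle Injury,gradual,1,no,match,index
P0014,2015-10-21,2015-16,Thigh,left,tendon,Hamstring Tendon Injury,gradual,9,no,training,index
P0014,2016-01-25,2015-16,Thigh,left,muscle,Hamstring Muscle Injury,sudden,12,no,match,index
P0014,2016-07-03,2016-17,Lower Leg,left,tendon,Achilles Tendinopathy,sudden,32,no,not_applicable,index
P0014,2017-01-05,2016-17,Trunk,left,muscle,Trunk Muscle Injury,sudden,2,no,training,index
P0014,2017-02-06,2016-17,TRUNK,left,MUSCLE,Trunk Muscle Injury,sudden,7,no,match,reinjury
P0014,2017-04-22,2016-17,ANKLE,left,LIGAMENT,Ankle Sprain,sudden,10,no,training,index
P0015,2017-05-27,2016-17,Thigh,left,muscle,Hamstring Muscle Injury,gradual,16,no,not_applicable,index
P0016,2016-11-12,2016-17,Foot,left,ligament,Foot Ligament Injury,sudden,3,no,training,index
P0017,2015-10-22,2015-16,Lower Leg,left,muscle,Calf Muscle Injury,sudden,1,no,match,index
P0017,2016-01-15,2015-16,Shoulder,right,joint,Shoulder Joint Injury,sudden,1,no,match,index
P0018,2015-12-28,2015-16,Thigh,right,muscle,Hamstring Muscle Injury,sudden,1,no,not_applicable,index
P0018,2016-07-18,2016-17,Lower Leg,left,muscle,Calf Muscle Injury,sudden,24,no,training,index
P0019,2015-12-17,2015-16,Thigh,left,muscle,Hamstring Muscle Injury,sudden,19,no,training,index
P0019,2016-07-20,2016-17,Hip and Groin,right,muscle,Groin Muscle Injury,gradual,34,no,training,index
P0019,2016-08-27,2016-17,Trunk,right,muscle,Trunk Muscle Injury,sudden,8,no,match,index
P0019,2016-08-28,2016-17,Knee,left,tendon,Unsure,sudden,10,no,match,index
P0020,2016-05-26,2015-16,Thigh,right,muscle,Hamstring Muscle Injury,sudden,8,no,training,index
P0021,2016-03-07,2015-16,Lower Leg,left,muscle,Calf Muscle Injury,gradual,1,no,match,index
P0022,2016-04-14,2015-16,Ankle,right,joint,Ankle Joint Injury,sudden,6,no,training,index
P0022,2017-03-16,2016-17,Hip and Groin,right,muscle,Groin Muscle Injury,sudden,3,no,training,index
P0023,2015-07-03,2015-16,Lower Leg,right,muscle,Calf Muscle Injury,sudden,18,no,match,index
P0023,2016-02-13,2015-16,Hip and Groin,left,tendon,Groin Tendon Injury,sudden,10,no,not_applicable,index
P0023,2017-04-19,2016-17,Knee,right,ligament,ACL,sudden,5,no,training,index
P0024,2015-09-03,2015-16,THIGH,left,TENDON,Hamstring Tendon Injury,sudden,9,no,training,index
P0024,2017-03-19,2016-17,Ankle,right,ligament,Ankle Sprain,sudden,11,no,match,index
P0024,2017-05-24,2016-17,ankle,right,joint,Ankle Joint Injury,sudden,4,no,training,index
P0025,2015-09-25,2015-16,Thigh,right,muscle,Hamstring Muscle Injury,sudden,1,no,match,index
P0025,2017-04-04,2016-17,ANKLE,right,JOINT,Ankle Joint Injury,gradual,1,no,match,index
P0002,2016-10-10,2016-17,Lower Leg,left,muscle,Calf Muscle Injury,sudden,7,yes,training,index
P0003,2016-02-20,2015-16,Ankle,right,ligament,Ankle Sprain,gradual,3,yes,match,index
P0003,2016-03-21,2015-16,Ankle,right,ligament,Ankle Sprain,sudden,9,yes,not_applicable,index
P0010,2016-04-02,2015-16,Thigh,right,muscle,Hamstring Muscle Injury,sudden,5,yes,training,index
P0018,2015-11-24,2015-16,Thigh,left,muscle,Hamstring Muscle Injury,sudden,3,yes,not_applicable,index
P0023,2016-09-20,2016-17,Thigh,left,muscle,Hamstring Muscle Injury,sudden,7,yes,training,index
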